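# Readers/writers for the on-disk formats: expression TSV, signature TSV/GMT,
# clinical CSV. All writers emit '#'-prefixed provenance comment lines which
# the readers skip.

#' Read a gene x sample expression TSV
#'
#' Expects tab-separated text with a header row of sample identifiers and a
#' first column of gene identifiers. Lines starting with `#` are treated as
#' provenance comments and skipped.
#'
#' @param path file path.
#' @param genesInRows if `FALSE` the table is transposed after reading
#'   (samples were in rows).
#' @param state normalization state to record on the returned object.
#' @return A \linkS4class{ChemoExpr}.
#' @export
readExpression <- function(path, genesInRows = TRUE,
                           state = c("external_normalized", "raw_counts",
                                     "tmm_log2")) {
  state <- match.arg(state)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs an id column plus >=1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate identifiers in '%s': %s", basename(path),
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row %d (%s), column '%s'",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  if (any(is.na(num))) stop("missing values in expression matrix")
  dimnames(num) <- list(ids, colnames(vals))
  if (!genesInRows) num <- t(num)
  ChemoExpr(num, state = state)
}

#' Write a ChemoExpr to TSV
#'
#' Values are written with 17 significant digits so that a
#' write/read round-trip is bitwise lossless.
#'
#' @param x a \linkS4class{ChemoExpr} or numeric matrix.
#' @param path output file path.
#' @param comments optional character vector written as `# `-prefixed header
#'   lines (e.g. config hash and seed).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, comments = character()) {
  m <- if (is(x, "ChemoExpr")) exprValues(x) else as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (is(x, "ChemoExpr"))
    comments <- c(comments, sprintf("state: %s", normState(x)))
  if (length(comments)) writeLines(paste("#", comments), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a drug signature from TSV or GMT
#'
#' TSV format: two columns (gene, weight), with or without a header line.
#' GMT format (extension `.gmt`): a single set per line
#' (`name<TAB>description<TAB>gene1<TAB>gene2...`); all weights default to 1.
#'
#' @param path file path.
#' @param drug drug name to record; defaults to the file stem (TSV) or set
#'   name (GMT).
#' @return A \linkS4class{DrugSignature}.
#' @export
readSignature <- function(path, drug = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty signature file: %s", path))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    fields <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stop("GMT line needs name, description, >=1 gene")
    genes <- fields[-(1:2)]
    return(DrugSignature(drug %||% fields[1L], genes, rep(1, length(genes))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("signature TSV needs two columns")
  first <- suppressWarnings(as.numeric(parts[[1L]][2L]))
  if (is.na(first)) parts <- parts[-1L]  # header row
  if (length(parts) == 0L) stop(sprintf("empty signature file: %s", path))
  genes <- vapply(parts, `[`, character(1), 1L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (any(!is.finite(w)))
    stop(sprintf("non-finite weight for gene(s): %s",
                 paste(genes[!is.finite(w)], collapse = ", ")))
  if (all(w == 0)) stop("all signature weights are zero")
  DrugSignature(drug %||% sub("\\.[^.]*$", "", basename(path)), genes, w)
}

#' Write a DrugSignature as a two-column TSV
#'
#' @param sig a \linkS4class{DrugSignature}.
#' @param path output path.
#' @param comments optional `# `-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeSignature <- function(sig, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  writeLines("gene\tweight", con)
  writeLines(sprintf("%s\t%.17g", geneIds(sig), sigWeights(sig)), con)
  invisible(path)
}

#' Read a clinical cohort CSV
#'
#' Requires columns `id`, `arm`, `os_time`, `os_event`; optional
#' `pfs_time`/`pfs_event`, `response` (CR/PR/SD/PD), `purist`
#' (classical/basal-like) and arbitrary additional covariate columns.
#'
#' @param path file path.
#' @return A validated data.frame.
#' @export
readClinical <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  validateClinical(df)
}

#' Validate a clinical table
#'
#' @param df data.frame with at least `id`, `arm`, `os_time`, `os_event`.
#' @return `df`, with event flags coerced to 0/1 integer.
#' @export
validateClinical <- function(df) {
  need <- c("id", "arm", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("clinical table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$id)) stop("duplicate patient ids")
  for (tc in intersect(c("os_time", "pfs_time"), names(df))) {
    if (any(!is.finite(df[[tc]])) || any(df[[tc]] <= 0))
      stop(sprintf("%s must be positive", tc))
  }
  for (ec in intersect(c("os_event", "pfs_event"), names(df))) {
    if (!all(df[[ec]] %in% c(0, 1, FALSE, TRUE)))
      stop(sprintf("%s must be 0/1", ec))
    df[[ec]] <- as.integer(df[[ec]])
  }
  if ("response" %in% names(df) &&
      !all(is.na(df$response) | df$response %in% c("CR", "PR", "SD", "PD")))
    stop("response must be one of CR, PR, SD, PD")
  df
}

#' Write per-sample projection scores as CSV
#'
#' @param result a \linkS4class{ProjectionResult}.
#' @param drug drug label for the `drug` column.
#' @param path output path.
#' @param comments optional `# `-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeScores <- function(result, drug, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  writeLines("sample,drug,score,overlap_fraction", con)
  s <- sampleScores(result)
  writeLines(sprintf("%s,%s,%.17g,%.17g", names(s), drug, s,
                     overlapFraction(result)), con)
  invisible(path)
}
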