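# helper: wrap contribution matrices into a minimal valid decomposition
mkDecomp <- function(A, nGenes = 50, seed = 1, cohort = "c") {
  k <- nrow(A)
  S <- withSeed(seed, matrix(rnorm(nGenes * k), nGenes, k))
  S <- scale(S); attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  S <- matrix(as.numeric(S), nGenes, k,
              dimnames = list(sprintf("g%03d", 1:nGenes),
                              paste0("IC", 1:k)))
  new("ICADecomposition", geneContrib = S, sampleContrib = A,
      k = as.integer(k), seed = 1L, cohortId = cohort)
}

sampleNames <- function(n) sprintf("s%02d", seq_len(n))

test_that("identical decompositions match themselves with rho 1", {
  A <- withSeed(2, matrix(rnorm(4 * 12), 4, 12,
                          dimnames = list(NULL, sampleNames(12))))
  d <- mkDecomp(A)
  m <- matchComponents(d, d)
  expect_equal(nrow(m), 4L)
  expect_equal(m$pdc_component, m$pdx_component)
  expect_equal(m$rho, rep(1, 4))
})

test_that("component permutation and sign flips are recovered", {
  A <- withSeed(4, matrix(rnorm(4 * 12), 4, 12,
                          dimnames = list(NULL, sampleNames(12))))
  perm <- c(3, 1, 4, 2)
  A2 <- A[perm, ]
  A2[2, ] <- -A2[2, ]  # flips the component mapped from pdc index...
  d1 <- mkDecomp(A); d2 <- mkDecomp(A2)
  m <- matchComponents(d1, d2)
  m <- m[order(m$pdc_component), ]
  expect_equal(m$pdx_component, order(perm))
  flipped <- m$pdc_component[m$sign == -1]
  expect_equal(flipped, perm[2])
  expect_equal(abs(m$rho), rep(1, 4))
})

test_that("independent decompositions rarely match at a high threshold", {
  emptyish <- vapply(1:20, function(s) {
    A1 <- withSeed(s, matrix(rnorm(2 * 12), 2, 12,
                             dimnames = list(NULL, sampleNames(12))))
    A2 <- withSeed(s + 100, matrix(rnorm(2 * 12), 2, 12,
                                   dimnames = list(NULL, sampleNames(12))))
    nrow(matchComponents(mkDecomp(A1), mkDecomp(A2), threshold = 0.95))
  }, numeric(1))
  expect_gte(mean(emptyish == 0), 0.9)
  # null |rho| levels consistent with the permutation oracle scale
  nullRho <- withSeed(1, replicate(500, abs(cor(sample(12), sample(12),
                                                method = "spearman"))))
  expect_lt(quantile(nullRho, 0.5), 0.35)
})

test_that("fewer than 3 paired patients is an error", {
  A <- matrix(rnorm(2 * 12), 2, 12, dimnames = list(NULL, sampleNames(12)))
  d <- mkDecomp(A)
  expect_error(matchComponents(d, d, pairing = c(s01 = "s01", s02 = "s02")),
               "3 paired")
})

test_that("perfect anticorrelation is selected and oriented", {
  aucs <- setNames(c(0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55, 0.6,
                     0.65, 0.7, 0.75), sampleNames(12))
  A <- rbind(-aucs, withSeed(8, rnorm(12)))
  colnames(A) <- sampleNames(12)
  d <- mkDecomp(A)
  m <- matchComponents(d, d)
  rc <- selectResponseComponent(m, d, aucs, adjust = "none")
  expect_equal(rc$component, 1L)
  expect_equal(rc$rho, -1)
  expect_equal(rc$orientation, 1)  # already sensitive-positive
  # positively correlated component gets flipped
  A2 <- rbind(aucs + withSeed(9, rnorm(12, sd = 1e-3)),
              withSeed(10, rnorm(12)))
  colnames(A2) <- sampleNames(12)
  d2 <- mkDecomp(A2)
  rc2 <- selectResponseComponent(matchComponents(d2, d2), d2, aucs,
                                 adjust = "none")
  expect_equal(rc2$orientation, -1)
  expect_gt(cor(rc2$orientation * A2[1, ], -aucs), 0.99)
})

test_that("the significant match with the largest |rho| wins", {
  aucs <- setNames(seq(0.2, 0.75, length.out = 12), sampleNames(12))
  strong <- -aucs
  weaker <- -aucs
  weaker[c(1, 12)] <- weaker[c(12, 1)]  # degrade the correlation
  A <- rbind(weaker, strong)
  colnames(A) <- sampleNames(12)
  d <- mkDecomp(A)
  rc <- selectResponseComponent(matchComponents(d, d), d, aucs,
                                adjust = "none")
  expect_equal(rc$component, 2L)
})

test_that("per-component selection is calibrated at alpha without a family", {
  hits <- vapply(1:300, function(s) {
    A <- withSeed(s, matrix(rnorm(12), 1, 12,
                            dimnames = list(NULL, sampleNames(12))))
    aucs <- setNames(withSeed(s + 500, runif(12)), sampleNames(12))
    d <- mkDecomp(A)
    m <- data.frame(pdc_component = 1L, pdx_component = 1L, rho = 1,
                    sign = 1)
    class(m) <- c("componentMatches", "data.frame")
    !inherits(tryCatch(selectResponseComponent(m, d, aucs,
                                               adjust = "none"),
                       error = function(e) e), "error")
  }, logical(1))
  expect_lt(mean(hits), 0.09)
  expect_gt(mean(hits), 0.015)
})

test_that("maxT keeps the family-wise null selection near alpha", {
  hits <- vapply(1:200, function(s) {
    A <- withSeed(s, matrix(rnorm(6 * 12), 6, 12,
                            dimnames = list(NULL, sampleNames(12))))
    aucs <- setNames(withSeed(s + 900, runif(12)), sampleNames(12))
    d <- mkDecomp(A)
    m <- data.frame(pdc_component = 1:6, pdx_component = 1:6,
                    rho = rep(1, 6), sign = rep(1, 6))
    class(m) <- c("componentMatches", "data.frame")
    !inherits(tryCatch(selectResponseComponent(m, d, aucs, nPerm = 499,
                                               permSeed = s),
                       error = function(e) e), "error")
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})
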