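# Shared fixtures and independent oracles, built in code at test time.

withSeed <- chemosig:::withSeed

# Small named count matrix.
tinyCounts <- function(nGenes = 20, nSamples = 4, seed = 42, lambda = 50) {
  withSeed(seed, {
    m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    m
  })
}

# Independent TMM oracle: direct evaluation of the doubly trimmed,
# precision-weighted mean of M-values (library-size-normalized log ratios),
# reference = sample whose upper quartile of scaled counts is closest to
# the mean upper quartile; factors recentered to geometric mean 1.
tmmOracle <- function(counts, trimM = 0.3, trimA = 0.05) {
  N <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    quantile(counts[, j] / N[j], 0.75, names = FALSE), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; Nr <- N[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]; Nj <- N[j]
    keep <- y > 0 & yr > 0
    M <- log2((y[keep] / Nj) / (yr[keep] / Nr))
    A <- 0.5 * log2((y[keep] / Nj) * (yr[keep] / Nr))
    v <- (Nj - y[keep]) / (Nj * y[keep]) + (Nr - yr[keep]) / (Nr * yr[keep])
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    kk <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(kk)) return(1)
    2^(sum(M[kk] / v[kk]) / sum(1 / v[kk]))  # inverse-variance weights
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Independent log-rank oracle: O-E with hypergeometric variance from the
# risk table, two groups.
logrankOracle <- function(times, events, group) {
  group <- as.integer(as.factor(group))
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    atRisk <- times >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Efron partial log-likelihood for a single covariate (1D oracle).
coxPartialLik <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# Random survival dataset with a score column.
randomSurvData <- function(n = 30, seed = 1) {
  withSeed(seed, {
    list(scores = setNames(rnorm(n), paste0("p", seq_len(n))),
         times = rexp(n, 0.1) + 0.01,
         events = rbinom(n, 1, 0.8))
  })
}

# Tiny planted-source matrix for ICA tests: X = S A + noise, leptokurtic
# sparse sources.
plantedSources <- function(nGenes = 100, nSamples = 24, k = 2, seed = 1,
                           noise = 0.1) {
  withSeed(seed, {
    S <- matrix(0, nGenes, k)
    for (j in seq_len(k)) {
      idx <- sample(nGenes, 10)
      S[idx, j] <- chemosig:::rlaplace(10) * 3
    }
    A <- matrix(rnorm(k * nSamples), k, nSamples)
    X <- S %*% A + matrix(rnorm(nGenes * nSamples, sd = noise),
                          nGenes, nSamples)
    dimnames(X) <- list(sprintf("g%03d", seq_len(nGenes)),
                        sprintf("s%02d", seq_len(nSamples)))
    list(X = X, S = S, A = A)
  })
}

# Tiny simulation spec for tests that only need latents/clinical machinery.
tinySpec <- function(seed = 1, ...) {
  simulationSpec(seed = seed, nGenes = 200,
                 supportSizes = c("5FU" = 10, oxaliplatin = 12,
                                  irinotecan = 8),
                 backgroundSupport = 20, ...)
}
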