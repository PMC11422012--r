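test_that("Kaplan-Meier product-limit hand values", {
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(medianSurvival(km), 2)

  kmC <- kmEstimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(kmC$surv == 1))
  expect_true(is.na(medianSurvival(kmC)))

  t <- withSeed(1, rexp(40, 0.1)); e <- withSeed(2, rbinom(40, 1, 0.7))
  a <- kmEstimate(t, e)
  b <- kmEstimate(c(t, t), c(e, e))
  expect_equal(a$surv, b$surv)
  expect_equal(a$time, b$time)
})

test_that("all-event untied KM steps are exactly (n - i)/n", {
  t <- withSeed(3, sort(runif(7)))
  km <- kmEstimate(t, rep(1, 7))
  expect_equal(km$surv, (7 - seq_len(7)) / 7)
})

test_that("log-rank matches a brute-force risk-table oracle", {
  lr <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  or <- logrankOracle(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_lt(abs(lr$chi2 - or$chi2), 1e-10)
  expect_lt(abs(lr$p - or$p), 1e-10)

  for (s in 1:20) {
    d <- randomSurvData(24, seed = s)
    g <- rep(c("A", "B"), each = 12)
    lr <- logrankTest(d$times, d$events, g)
    or <- logrankOracle(d$times, d$events, g)
    expect_lt(abs(lr$chi2 - or$chi2), 1e-10)
  }

  two <- logrankTest(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(two$chi2, 0, tolerance = 1e-12)
  expect_equal(two$p, 1)
  expect_error(logrankTest(1:4, rep(1, 4), rep("A", 4)), "2 groups")
})

test_that("log-rank p-values are calibrated under label permutation", {
  d <- randomSurvData(40, seed = 10)
  ps <- withSeed(77, vapply(1:500, function(i) {
    g <- sample(rep(c("A", "B"), each = 20))
    logrankTest(d$times, d$events, g)$p
  }, numeric(1)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("best cutpoint separates a constructed step in survival", {
  scores <- setNames(1:20, paste0("p", 1:20))
  times <- ifelse(scores > 10, 100, 10) * withSeed(4, runif(20, 0.9, 1.1))
  st <- suppressWarnings(bestCutpoint(scores, times, rep(1, 20)))
  expect_gt(st$cutpoint, 10)
  expect_lt(st$cutpoint, 11)
  expect_true(all(st$labels[scores > st$cutpoint]))
  expect_error(bestCutpoint(setNames(rep(1, 20), paste0("p", 1:20)),
                            times, rep(1, 20)), "distinct")
})

test_that("best cutpoint agrees with an exhaustive-scan oracle", {
  for (s in 1:50) {
    d <- randomSurvData(30, seed = s + 200)
    st <- bestCutpoint(d$scores, d$times, d$events)
    su <- sort(unique(d$scores))
    cuts <- (su[-1] + su[-length(su)]) / 2
    cuts <- cuts[vapply(cuts, function(ct) {
      hi <- sum(d$scores > ct); min(hi, 30 - hi) >= 3 - 1e-9
    }, logical(1))]
    ps <- vapply(cuts, function(ct)
      logrankTest(d$times, d$events, d$scores > ct)$p, numeric(1))
    expect_equal(st$p, min(ps), tolerance = 1e-12)
    # reported p equals the log-rank recomputed at the returned cutpoint
    expect_equal(st$p,
                 logrankTest(d$times, d$events,
                             d$scores > st$cutpoint)$p,
                 tolerance = 1e-12)
  }
})

test_that("maximally-selected adjusted p is conservative under the null", {
  rejected <- vapply(1:60, function(s) {
    d <- randomSurvData(60, seed = s + 900)
    bestCutpoint(d$scores, d$times, d$events)$adjustedP < 0.05
  }, logical(1))
  expect_lte(mean(rejected), 0.12)
})

test_that("Cox fit symmetry properties", {
  t <- withSeed(5, rexp(30, 0.1)); e <- rep(1, 30)
  # identical survival in both label groups: HR exactly 1
  fit <- coxFit(data.frame(x = rep(c(0, 1), each = 30)), c(t, t), c(e, e))
  expect_equal(fit$hr, 1, tolerance = 1e-8)

  d <- randomSurvData(40, seed = 30)
  x <- as.integer(d$scores > median(d$scores))
  f1 <- coxFit(data.frame(x = x), d$times, d$events)
  f2 <- coxFit(data.frame(x = 1 - x), d$times, d$events)
  expect_lt(abs(f1$beta + f2$beta), 1e-10)
})

test_that("Cox Newton solution matches a 1D partial-likelihood maximizer", {
  for (s in 1:5) {
    d <- randomSurvData(25, seed = s + 40)
    x <- withSeed(s, rnorm(25))
    fit <- coxFit(data.frame(x = x), d$times, d$events)
    opt <- optimize(function(b) coxPartialLik(b, x, d$times, d$events),
                    c(-5, 5), maximum = TRUE, tol = 1e-10)
    expect_lt(abs(fit$beta - opt$maximum), 1e-6)
  }
})

test_that("Cox preconditions and separation diagnostics", {
  d <- randomSurvData(20, seed = 60)
  expect_error(coxFit(data.frame(x = rep(1, 20)), d$times, d$events),
               "constant")
  # monotone likelihood: all early events in one group
  t <- c(1:10, 101:110); e <- rep(1, 20)
  x <- rep(c(1, 0), each = 10)
  expect_error(suppressWarnings(coxFit(data.frame(x = x), t, e)),
               "separation")
})

test_that("IPTW weights of one reproduce the unweighted curves", {
  d <- randomSurvData(60, seed = 70)
  g <- rep(c("A", "B"), 30)
  out <- iptwAdjustedKM(g, d$times, d$events, weights = rep(1, 60))
  expect_equal(out$adjusted$A$surv, out$unadjusted$A$surv)
  expect_equal(out$adjusted$B$surv, out$unadjusted$B$surv)
})

test_that("perfect propensity separation is rejected", {
  n <- 40
  g <- rep(c("A", "B"), each = n / 2)
  x <- ifelse(g == "A", 0, 10) + withSeed(1, rnorm(n, sd = 0.01))
  expect_error(
    iptwAdjustedKM(g, rexp(n, 0.1), rep(1, n), data.frame(x = x)),
    "separation")
})

test_that("IPTW with unconfounded covariates changes little", {
  n <- 500
  withSeed(80, {
    cov <- data.frame(age = rnorm(n, 65, 8), sex = rbinom(n, 1, 0.5))
    g <- rep(c("A", "B"), length.out = n)
    t <- rexp(n, 0.1); e <- rbinom(n, 1, 0.8)
    out <- iptwAdjustedKM(g, t, e, cov)
    for (grp in c("A", "B")) {
      adj <- out$adjusted[[grp]]; un <- out$unadjusted[[grp]]
      expect_lt(max(abs(adj$surv - un$surv)), 0.02)
    }
  })
})

test_that("IPTW removes a planted confounder's distortion", {
  closer <- vapply(1:10, function(s) withSeed(s + 300, {
    n <- 400
    L <- rnorm(n)
    g <- rbinom(n, 1, plogis(1.5 * L))        # confounder drives group
    t <- rexp(n, 0.08 * exp(0.9 * L))          # and hazard, group is null
    e <- rep(1, n)
    out <- iptwAdjustedKM(factor(g), t, e, data.frame(L = L))
    grid <- seq(0.5, 20, 0.5)
    ev <- function(km) approx(c(0, km$time), c(1, km$surv), grid,
                              method = "constant", rule = 2)$y
    dAdj <- max(abs(ev(out$adjusted[["0"]]) - ev(out$adjusted[["1"]])))
    dUn <- max(abs(ev(out$unadjusted[["0"]]) - ev(out$unadjusted[["1"]])))
    dAdj < dUn
  }), logical(1))
  expect_gte(mean(closer), 0.8)
})

test_that("exact binomial ORR: closed forms and beta-quantile oracle", {
  none <- orrExact(rep("PD", 10), p0 = 0.3)
  expect_equal(none$orr, 0)
  expect_equal(none$ciLow, 0)
  expect_equal(none$ciHigh, 1 - 0.025^(1 / 10), tolerance = 1e-10)

  all10 <- orrExact(rep(c("CR", "PR"), 5), p0 = 0.3)
  expect_equal(all10$ciHigh, 1)

  half <- orrExact(c(rep("PR", 5), rep("SD", 5)), p0 = 0.2)
  expect_equal(half$ciLow, qbeta(0.025, 5, 6), tolerance = 1e-12)
  expect_equal(half$ciHigh, qbeta(0.975, 6, 5), tolerance = 1e-12)
  expect_equal(half$ciLow, 1 - half$ciHigh, tolerance = 1e-12)

  # p0 defaults to the pooled ORR; the group argument subsets
  resp <- c(rep("PR", 4), rep("PD", 12))
  o <- orrExact(resp, group = 1:8)
  expect_equal(o$p0, 0.25)
  expect_equal(o$n, 8L)
  # CI always contains the point estimate, and narrows with n
  expect_true(o$ciLow <= o$orr && o$orr <= o$ciHigh)
  wide <- orrExact(c(rep("PR", 3), rep("PD", 3)), p0 = 0.5)
  narrow <- orrExact(c(rep("PR", 30), rep("PD", 30)), p0 = 0.5)
  expect_lt(narrow$ciHigh - narrow$ciLow, wide$ciHigh - wide$ciLow)
})

test_that("chi-square matches hand computation and the O-E oracle", {
  flat <- chiSquareTest(matrix(c(50, 50, 50, 50), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  t22 <- suppressWarnings(chiSquareTest(matrix(c(10, 20, 20, 10), 2)))
  expect_equal(t22$chi2, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(t22$df, 1)

  tab <- withSeed(90, matrix(rpois(12, 30), 3, 4))
  res <- chiSquareTest(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_equal(res$df, 6)

  expect_error(chiSquareTest(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_warning(chiSquareTest(matrix(c(2, 3, 4, 1), 2)), "below 5")
})

test_that("drug label combination counts and encodes correctly", {
  ids <- paste0("p", 1:6)
  labs <- list(
    `5FU` = setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), ids),
    oxaliplatin = setNames(c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE), ids),
    irinotecan = setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), ids))
  prof <- combineDrugLabels(labs)
  expect_equal(prof$sensitiveCount, c(2, 3, 0, 1, 3, 0))
  expect_identical(levels(prof$countFactor)[1], "0")
  bad <- labs; names(bad[[3]])[1] <- "zz"
  expect_error(combineDrugLabels(bad), "mismatched")
})

test_that("sensitive-count hazard ordering is recovered by Cox", {
  okOrder <- vapply(1:20, function(s) withSeed(s + 700, {
    n <- 300
    cnt <- sample(0:3, n, replace = TRUE)
    hr <- c(1, 0.7, 0.4, 0.12)[cnt + 1]
    t <- rexp(n, 0.1 * hr)
    fit <- coxFit(data.frame(count = factor(cnt)), t, rep(1, n))
    all(diff(fit$hr) < 0)  # HR(1) > HR(2) > HR(3)
  }), logical(1))
  expect_gte(mean(okOrder), 0.9)
})
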