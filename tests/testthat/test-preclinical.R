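test_that("flat viability panels fit as inactive drug with full AUC", {
  doses <- 10^seq(-9, -3, length.out = 7)
  p <- doseResponsePanel(rep(doses, 3), rep(1, 21))
  fit <- fitDoseResponse(p)
  expect_true(fit$converged)
  expect_equal(fit$upper, 1, tolerance = 1e-9)
  expect_equal(fit$lower, 1, tolerance = 1e-9)
  expect_equal(viabilityAUC(fit)$value, 1, tolerance = 1e-9)

  p0 <- doseResponsePanel(rep(doses, 3), rep(0, 21))
  expect_equal(viabilityAUC(fitDoseResponse(p0))$value, 0, tolerance = 1e-9)
})

test_that("4PL parameters are recovered from noisy panels", {
  doses <- 10^seq(-9, -3, length.out = 9)
  ok <- withSeed(11, vapply(1:100, function(i) {
    v <- chemosig:::.fourPL(log10(rep(doses, 3)), 1, 0, -6, 1) +
      rnorm(27, sd = 0.02)
    fit <- fitDoseResponse(doses = rep(doses, 3), viability = pmax(v, 0))
    fit$converged && abs(log10(fit$ec50) - (-6)) < log10(2)
  }, logical(1)))
  expect_gte(mean(ok), 0.95)
})

test_that("step-like data place the EC50 inside the step interval", {
  doses <- 10^seq(-9, -3, length.out = 9)
  v <- ifelse(doses < 1e-6, 1, 0)
  fit <- fitDoseResponse(doses = doses, viability = v)
  step <- sort(log10(doses[doses >= 10^-6.75 & doses <= 10^-5.2]))
  expect_gte(log10(fit$ec50), -6.9)
  expect_lte(log10(fit$ec50), -5.1)
})

test_that("AUC of a steep symmetric 4PL at the range midpoint is 1/2", {
  fit <- structure(list(upper = 1, lower = 0, ec50 = 1e-6, hill = 60,
                        rss = 0, converged = TRUE,
                        predict = function(lx)
                          chemosig:::.fourPL(lx, 1, 0, -6, 60)),
                   class = "sigmoidFit")
  expect_equal(viabilityAUC(fit)$value, 0.5, tolerance = 1e-3)
  # independent numeric oracle on a fine grid
  xg <- seq(-9, -3, length.out = 20001)
  oracle <- chemosig:::trapz(xg, fit$predict(xg)) / 6
  expect_equal(viabilityAUC(fit)$value, oracle, tolerance = 1e-4)
})

test_that("viability AUC is monotone in the viability curve", {
  mk <- function(lower) structure(
    list(upper = 1, lower = lower, ec50 = 1e-6, hill = 1, rss = 0,
         converged = TRUE,
         predict = function(lx) chemosig:::.fourPL(lx, 1, lower, -6, 1)),
    class = "sigmoidFit")
  expect_lt(viabilityAUC(mk(0))$value, viabilityAUC(mk(0.3))$value)
})

test_that("growth-rate correction transforms viability before integration", {
  fit <- structure(list(upper = 1, lower = 0.2, ec50 = 1e-6, hill = 1,
                        rss = 0, converged = TRUE,
                        predict = function(lx)
                          chemosig:::.fourPL(lx, 1, 0.2, -6, 1)),
                   class = "sigmoidFit")
  xg <- seq(-9, -3, length.out = 201)
  v <- fit$predict(xg)
  gr <- (pmin(pmax(2^(log2(v) / 2) - 1, -1), 1) + 1) / 2
  oracle <- chemosig:::trapz(xg, gr) / 6
  expect_equal(viabilityAUC(fit, replicationRate = 2)$value, oracle,
               tolerance = 1e-9)
  nc <- fit; nc$converged <- FALSE
  expect_error(viabilityAUC(nc), "rawTrapezoidAUC")
})

test_that("non-convergent panels fall back to the raw trapezoid", {
  doses <- 10^seq(-9, -3, length.out = 7)
  v <- c(1, 1, 1, 0.5, 0, 0, 0)
  raw <- rawTrapezoidAUC(doses, v)
  xg <- sort(log10(doses))
  expect_equal(raw, chemosig:::trapz(xg, v) / 6, tolerance = 1e-12)
})

test_that("panel preconditions are enforced", {
  expect_error(doseResponsePanel(10^(-5:-1), c(1, 1, -0.1, 0, 0)), ">= 0")
  expect_error(doseResponsePanel(rep(1e-6, 6), rep(1, 6)), "5 distinct")
})

test_that("constant growth curves fit as flat volume", {
  g <- growthCurveSet(data.frame(day = rep(seq(0, 30, 5), 2),
                                 volume = 200,
                                 mouse = rep(c("m1", "m2"), each = 7)))
  fit <- fitGrowthCurve(g)
  expect_equal(fit$predict(c(0, 15, 30)), rep(200, 3), tolerance = 1e-9)
})

test_that("logistic growth parameters are recovered", {
  days <- seq(0, 60, 4)
  ok <- withSeed(5, vapply(1:50, function(i) {
    v <- 1500 / (1 + exp(-0.1 * (days - 30))) * exp(rnorm(length(days),
                                                          sd = 0.05))
    fit <- fitGrowthCurve(growthCurveSet(data.frame(day = days,
                                                    volume = v)))
    abs(fit$Vmax / 1500 - 1) < 0.1 && abs(fit$k / 0.1 - 1) < 0.25 &&
      abs(fit$t0 / 30 - 1) < 0.1
  }, logical(1)))
  expect_gte(mean(ok), 0.9)
})

test_that("monotone-decreasing growth pins Vmax at the initial volume", {
  days <- seq(0, 30, 5)
  g <- growthCurveSet(data.frame(day = days,
                                 volume = 600 * exp(-0.08 * days)))
  fit <- fitGrowthCurve(g)
  expect_true("decreasing" %in% fit$flags)
  expect_equal(fit$Vmax, 600, tolerance = 1e-6)
})

test_that("duplicating a mouse leaves the fit unchanged", {
  days <- seq(0, 40, 5)
  v <- 800 / (1 + exp(-0.15 * (days - 20)))
  one <- growthCurveSet(data.frame(day = days, volume = v, mouse = "m1"))
  two <- growthCurveSet(data.frame(day = rep(days, 2), volume = rep(v, 2),
                                   mouse = rep(c("m1", "m2"),
                                               each = length(days))))
  f1 <- fitGrowthCurve(one); f2 <- fitGrowthCurve(two)
  expect_equal(f1$Vmax, f2$Vmax, tolerance = 1e-6)
  expect_equal(f1$k, f2$k, tolerance = 1e-6)
})

test_that("volumes above 2000 mm3 are censored thereafter", {
  g <- growthCurveSet(data.frame(day = c(0, 10, 20, 30),
                                 volume = c(500, 2500, 900, 900)))
  expect_identical(g$data$censored, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tumorVolume(10, 5), 125)
})

test_that("POR trivial and hand-computed cases", {
  days <- 0:10
  ctrl <- growthCurveSet(data.frame(day = days, volume = 20 * days),
                         pdxId = "x1", arm = "control")
  trt <- growthCurveSet(data.frame(day = days, volume = rep(50, 11)),
                        pdxId = "x1", arm = "treated")
  expect_equal(por(trt, ctrl, method = "raw")$value, 0.5,
               tolerance = 1e-12)

  same <- growthCurveSet(data.frame(day = days,
                                    volume = 300 / (1 + exp(-(days - 5)))),
                         pdxId = "x1", arm = "control")
  sameT <- same; sameT$arm <- "treated"
  expect_equal(por(sameT, same)$value, 1, tolerance = 1e-9)

  zero <- growthCurveSet(data.frame(day = days, volume = rep(0, 11)),
                         pdxId = "x1", arm = "treated")
  expect_equal(por(zero, ctrl, method = "raw")$value, 0)
  expect_error(por(trt, zero, method = "raw"), "control AUC")
  trt2 <- trt; trt2$pdxId <- "x2"
  expect_error(por(trt2, ctrl), "mismatched")
})

test_that("POR is invariant to a common volume scale", {
  # keep scaled volumes below the 2000 mm3 censoring threshold
  days <- seq(0, 40, 4)
  v1 <- withSeed(2, 300 / (1 + exp(-0.12 * (days - 18))) *
                   exp(rnorm(length(days), sd = 0.05)))
  v2 <- withSeed(3, 180 / (1 + exp(-0.12 * (days - 18))) *
                   exp(rnorm(length(days), sd = 0.05)))
  c1 <- growthCurveSet(data.frame(day = days, volume = v1), "x", "control")
  t1 <- growthCurveSet(data.frame(day = days, volume = v2), "x", "treated")
  c2 <- growthCurveSet(data.frame(day = days, volume = 3 * v1), "x",
                       "control")
  t2 <- growthCurveSet(data.frame(day = days, volume = 3 * v2), "x",
                       "treated")
  expect_equal(por(t1, c1)$value, por(t2, c2)$value, tolerance = 1e-6)
})

test_that("discovery selection matches the type-7 percentile oracle", {
  aucs <- setNames((1:40) / 40, sprintf("m%02d", 1:40))
  sel <- selectDiscoverySamples(aucs)
  q <- quantile(aucs, c(0.10, 0.25, 0.75, 0.90), type = 7)
  expect_identical(sel$sensitive, sprintf("m%02d", 5:10))
  expect_identical(sel$resistant, sprintf("m%02d", 31:36))
  expect_true(all(aucs[sel$sensitive] >= q[1] & aucs[sel$sensitive] <= q[2]))
  # disjoint, non-overlapping AUC ranges
  expect_length(intersect(sel$sensitive, sel$resistant), 0L)
  expect_lt(max(aucs[sel$sensitive]), min(aucs[sel$resistant]))
})

test_that("discovery selection degenerate cases error", {
  expect_error(selectDiscoverySamples(setNames(rep(1, 15),
                                               paste0("s", 1:15))),
               "degenerate")
  expect_error(selectDiscoverySamples(setNames(1:12, paste0("s", 1:12))),
               "enlarge")
  # oversized band: keeps the 6 closest to the band midpoint
  aucs <- setNames(seq(0, 1, length.out = 80), sprintf("n%02d", 1:80))
  sel <- selectDiscoverySamples(aucs)
  expect_length(sel$sensitive, 6L)
  expect_length(sel$resistant, 6L)
})
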