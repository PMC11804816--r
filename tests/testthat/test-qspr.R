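test_that("linear fit reproduces the published complexity ~ GA4 statistics", {
  props <- drugProperties()
  idx <- paperIndices()
  fit <- fitPropertyModel(idx$ga4, props$C, "linear")
  expect_equal(fit@alpha, -81.90, tolerance = 0.01)
  expect_equal(fit@beta, 20.49, tolerance = 0.01)
  expect_equal(fit@r, 0.6602, tolerance = 0.005 / 0.6602)
  expect_equal(fit@f, 8.498, tolerance = 0.01)
  expect_equal(fit@p, 0.01406, tolerance = 0.01)
  fl <- significance(fit)
  expect_true(fl[["p_ok"]])
  expect_true(fl[["f_ok"]])
  expect_false(fl[["r_ok"]])
  expect_false(fl[["overall"]])
})

test_that("quadratic fit reproduces the published complexity ~ GA4 statistics", {
  props <- drugProperties()
  idx <- paperIndices()
  fit <- fitPropertyModel(idx$ga4, props$C, "quadratic")
  expect_equal(fit@r, 0.6831, tolerance = 0.005 / 0.6831)
  expect_equal(fit@f, 4.376, tolerance = 0.01)
  expect_equal(fit@alpha, 1276.795, tolerance = 0.01)
  expect_equal(fit@beta, -74.313, tolerance = 0.01)
  expect_equal(fit@gamma, 1.629, tolerance = 0.01)
})

test_that("perfect fits are reported with r = 1 and a guarded F", {
  x <- 1:10
  lin <- fitPropertyModel(x, 2 * x + 1, "linear")
  expect_equal(lin@alpha, 1)
  expect_equal(lin@beta, 2)
  expect_equal(lin@r2, 1)
  expect_equal(lin@r, 1)
  expect_equal(lin@f, Inf)
  expect_equal(lin@p, 0)
  expect_true(significance(lin)[["r_ok"]])

  quad <- fitPropertyModel(x, x^2, "quadratic")
  expect_equal(quad@alpha, 0, tolerance = 1e-8)
  expect_equal(quad@beta, 0, tolerance = 1e-8)
  expect_equal(quad@gamma, 1, tolerance = 1e-10)
  expect_equal(quad@r2, 1)
})

test_that("linear r equals |Pearson correlation| by the covariance formula", {
  dat <- randomRegressionData(13, alpha = 5, beta = 0, noiseSd = 2, seed = 99)
  x <- dat$x
  y <- dat$y
  fit <- fitPropertyModel(x, y, "linear")
  # textbook covariance-based Pearson correlation, computed from scratch
  pearson <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit@r, abs(pearson), tolerance = 1e-12)
  expect_equal(fit@r2, pearson^2, tolerance = 1e-12)

  # negative-slope data: r is still reported non-negative, slope keeps sign
  fitNeg <- fitPropertyModel(x, -3 * x + rnorm(13), "linear")
  expect_gt(fitNeg@r, 0)
  expect_lt(fitNeg@beta, 0)
})

test_that("overall F agrees with the slope t-test for one predictor", {
  props <- drugProperties()
  idx <- paperIndices()
  for (col in c("zeta", "ga4", "he")) {
    fit <- fitPropertyModel(idx[[col]], props$BP, "linear")
    tval <- summary(stats::lm(props$BP ~ idx[[col]]))$coefficients[2, "t value"]
    expect_equal(fit@f, tval^2, tolerance = 1e-10)
  }
})

test_that("residuals are orthogonal to the design columns", {
  dat <- randomRegressionData(50, alpha = 2, beta = -1, gamma = 0.3,
                              noiseSd = 4, seed = 3)
  fit <- fitPropertyModel(dat$x, dat$y, "quadratic")
  res <- dat$y - (fit@alpha + fit@beta * dat$x + fit@gamma * dat$x^2)
  X <- cbind(1, dat$x, dat$x^2)
  expect_true(all(abs(crossprod(X, res)) < 1e-6 * max(abs(dat$y))))
})

test_that("quadratic fits recover known coefficients within 3 standard errors", {
  truth <- c(alpha = 40, beta = -6, gamma = 0.8)
  dat <- randomRegressionData(200, alpha = truth["alpha"],
                              beta = truth["beta"], gamma = truth["gamma"],
                              noiseSd = 1, seed = 2024)
  fit <- fitPropertyModel(dat$x, dat$y, "quadratic")
  se <- summary(stats::lm(dat$y ~ dat$x + I(dat$x^2)))$coefficients[, "Std. Error"]
  est <- c(fit@alpha, fit@beta, fit@gamma)
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("F statistic closed form and p-values match their oracles", {
  expect_equal(fStatistic(0.4359, 13, 1), 8.50, tolerance = 0.001)
  expect_equal(fStatistic(0, 13, 1), 0)
  expect_equal(fStatistic(0.4667, 13, 2), 4.376, tolerance = 0.001)
  expect_error(fStatistic(1, 13, 1), "infinite")

  expect_equal(pFromF(8.498, 1, 11), 0.01406, tolerance = 0.001)
  expect_equal(pFromF(0, 1, 11), 1)
  # quadrature oracle: integrate the F density over the upper tail
  quadrature <- stats::integrate(function(x) stats::df(x, 2, 10),
                                 lower = 3, upper = Inf)$value
  expect_equal(pFromF(3, 2, 10), quadrature, tolerance = 1e-6)
})

test_that("significance screen uses strict F and r thresholds", {
  fit <- new("RegressionFit", kind = "linear", alpha = 0, beta = 1,
             gamma = NA_real_, r = sqrt(0.45), r2 = 0.45, f = 2.5, p = 0.04,
             n = 13L)
  fl <- significance(fit)
  expect_false(fl[["f_ok"]])  # boundary: strictly greater than 2.5
  expect_true(fl[["p_ok"]])   # boundary: p <= 0.05 passes
  expect_false(fl[["r_ok"]])
})

test_that("degenerate designs are rejected", {
  expect_error(fitPropertyModel(rep(2, 10), rnorm(10), "linear"), "constant")
  expect_error(fitPropertyModel(1:5, 1:4, "linear"), "lengths differ")
  expect_error(fitPropertyModel(rep(c(1, 2), 5), rnorm(10), "quadratic"),
               "rank-deficient|constant")
  expect_error(fitPropertyModel(1:3, rnorm(3), "quadratic"), "at least")
})

test_that("fitAllModels crosses every index with every property", {
  props <- drugProperties()
  idx <- paperIndices()
  fits <- fitAllModels(idx, props)
  expect_equal(nrow(fits), 8 * 8 * 2)
  expect_true(all(fits$n == 13))
  expect_true(all(fits$r >= 0 & fits$r <= 1))
  # the single published screen-passing combination
  sig <- fits[!is.na(fits$p_ok) & fits$p_ok & fits$f_ok & fits$model == "linear", ]
  expect_true(all(sig$index == "ga4" & sig$property == "C"))

  linOnly <- fitAllModels(idx, props, models = "linear")
  expect_equal(unique(linOnly$model), "linear")
  expect_equal(nrow(linOnly), 64)

  expect_error(fitAllModels(idx[1:10, ], props), "do not match")
})

test_that("correlation tables mirror the published layout and nesting", {
  props <- drugProperties()
  idx <- paperIndices()
  lin <- correlationTable(idx, props, "linear")
  quad <- correlationTable(idx, props, "quadratic")
  expect_equal(dim(lin), c(8, 8))
  expect_equal(colnames(lin), c("BP", "MP", "E", "FP", "MR", "C", "MW", "R"))
  expect_equal(lin["ga4", "C"], 0.6602)
  expect_equal(quad["ga4", "C"], 0.6831, tolerance = 2e-4)  # printed digit truncated
  # nested models: quadratic r never below linear r (recomputed tables)
  expect_true(all(quad >= lin - 1e-9))
  # self-regression sanity: a column regressed on itself correlates perfectly
  selfFit <- fitPropertyModel(idx$ga4, idx$ga4, "linear")
  expect_equal(selfFit@r, 1)
})
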