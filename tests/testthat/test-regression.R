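# Regression families, body-weight adjustment, and the damage/pelvic model
# surfaces.

test_that("body-weight adjustment removes the correlation, keeps the mean", {
  set.seed(51)
  n <- 2000
  bw <- rnorm(n, 2000, 180)
  # perfectly linear pelvic -> adjusted collapses to the mean
  pel <- 10 + 0.02 * bw
  adj <- adjustForBodyweight(pel, bw)
  expect_true(all(abs(adj - mean(pel)) < 1e-9))
  # independent pelvic -> essentially unchanged
  pel2 <- rnorm(n, 40, 5)
  adj2 <- adjustForBodyweight(pel2, bw)
  expect_gt(cor(adj2, pel2), 0.999)
  # corr 0.65 scenario -> post-adjustment correlation < 0.05
  z <- matrix(rnorm(2 * n), ncol = 2) %*%
    chol(matrix(c(1, 0.65, 0.65, 1), 2))
  pel3 <- 40.43 + 5.3 * z[, 1]
  bw3 <- 2000 + 180 * z[, 2]
  adj3 <- adjustForBodyweight(pel3, bw3)
  expect_lt(abs(cor(adj3, bw3)), 0.05)
  expect_equal(mean(adj3), mean(pel3))
  expect_error(adjustForBodyweight(pel3, rep(1, n)), "constant")
})

test_that("linear fit is exact on noiseless data", {
  x <- 1:20
  fit <- fitLinear(3 + 2 * x, data.frame(x = x))
  expect_equal(unname(coef(fit)), c(3, 2), tolerance = 1e-10)
  # intercept-only returns the mean
  y <- rnorm(30)
  fit0 <- fitLinear(y, data.frame()[seq_along(y), , drop = FALSE])
  expect_equal(unname(coef(fit0)[1]), mean(y))
  # collinearity is named
  expect_error(fitLinear(rnorm(20), data.frame(a = x, b = 2 * x)),
               "collinear")
})

test_that("linear Wald intervals cover at the nominal rate", {
  hits <- 0
  trials <- 0
  for (i in 1:300) {
    set.seed(700 + i)
    X <- data.frame(x1 = rnorm(120), x2 = rnorm(120))
    y <- 1 + 0.5 * X$x1 - 0.2 * X$x2 + rnorm(120)
    cf <- tidyCoef(fitLinear(y, X))
    truth <- c(1, 0.5, -0.2)
    hits <- hits + sum(abs(cf$estimate - truth) <= 2 * cf$se)
    trials <- trials + 3
  }
  expect_gt(hits / trials, 0.93)
  expect_lt(hits / trials, 0.98)
})

test_that("logistic fit recovers simulated effects and intercepts", {
  set.seed(53)
  # intercept-only with prevalence 0.75 -> b0 = log 3
  y <- rep(c(1, 0), c(75, 25))
  fit0 <- fitLogistic(y, data.frame()[seq_along(y), , drop = FALSE])
  expect_equal(unname(coef(fit0)[1]), log(3), tolerance = 1e-6)
  # slope recovery
  x <- rnorm(2000)
  y1 <- rbinom(2000, 1, plogis(-0.3 + 1 * x))
  fit1 <- fitLogistic(y1, data.frame(x = x))
  expect_lt(abs(coef(fit1)["x"] - 1), 0.15)
  # independence -> slope near zero
  y2 <- rbinom(2000, 1, 0.5)
  fit2 <- fitLogistic(y2, data.frame(x = x))
  expect_lt(abs(coef(fit2)["x"]), 0.15)
  # separation is flagged
  ys <- as.integer(x > 0)
  expect_warning(fits <- fitLogistic(ys, data.frame(x = x)), "separation")
  expect_false(fits@converged)
})

test_that("censored Poisson reduces to the Poisson MLE without censoring", {
  set.seed(59)
  y <- rpois(400, 3)
  none <- rep(FALSE, 400)
  X0 <- data.frame()[seq_along(y), , drop = FALSE]
  fit <- fitCensoredPoisson(y, none, X0, censorPoint = max(y) + 1)
  expect_equal(unname(exp(coef(fit)[1])), mean(y), tolerance = 1e-6)
  # identical to uncensored glm including the log-likelihood
  glmFit <- glm(y ~ 1, family = poisson())
  expect_equal(logLik(fit), as.numeric(stats::logLik(glmFit)),
               tolerance = 1e-9)
  # with covariates too
  x <- rnorm(400)
  y2 <- rpois(400, exp(0.5 + 0.3 * x))
  fit2 <- fitCensoredPoisson(y2, rep(FALSE, 400), data.frame(x = x),
                             censorPoint = max(y2) + 1)
  glm2 <- glm(y2 ~ x, family = poisson())
  expect_equal(unname(coef(fit2)), unname(coef(glm2)), tolerance = 1e-6)
  expect_equal(logLik(fit2), as.numeric(stats::logLik(glm2)),
               tolerance = 1e-9)
})

test_that("censored Poisson matches a grid-search oracle", {
  set.seed(61)
  lamTrue <- 2
  cp <- 4
  yRaw <- rpois(5000, lamTrue)
  cens <- yRaw >= cp
  y <- pmin(yRaw, cp)
  X0 <- data.frame()[seq_along(y), , drop = FALSE]
  fit <- fitCensoredPoisson(y, cens, X0, censorPoint = cp)
  lamHat <- unname(exp(coef(fit)[1]))
  expect_lt(abs(lamHat - lamTrue), 0.1)
  # independent 1-D grid search over lambda
  negLL <- function(l) {
    -(sum(dpois(y[!cens], l, log = TRUE)) +
        sum(rep(ppois(cp - 1, l, lower.tail = FALSE, log.p = TRUE),
                sum(cens))))
  }
  grid <- seq(1.5, 2.5, by = 1e-5)
  oracle <- grid[which.min(vapply(grid, negLL, 1))]
  expect_lt(abs(lamHat - oracle), 1e-4)
  # guards
  expect_error(fitCensoredPoisson(y, rep(TRUE, 5000), X0, cp), "censored")
  badFlags <- cens
  badFlags[which(y == 1)[1]] <- TRUE
  expect_error(fitCensoredPoisson(y, badFlags, X0, cp), "censor point")
})

test_that("censored Poisson Wald intervals cover near nominal", {
  hits <- 0
  trials <- 0
  for (i in 1:300) {
    set.seed(900 + i)
    x <- rnorm(150)
    yRaw <- rpois(150, exp(log(2) + 0.3 * x))
    cens <- yRaw >= 4
    y <- pmin(yRaw, 4)
    cf <- tidyCoef(fitCensoredPoisson(y, cens, data.frame(x = x), 4))
    truth <- c(log(2), 0.3)
    hits <- hits + sum(abs(cf$estimate - truth) <= 2 * cf$se)
    trials <- trials + 2
  }
  expect_gt(hits / trials, 0.93)
  expect_lt(hits / trials, 0.98)
})

test_that("fitters are equivariant to affine predictor rescaling", {
  set.seed(63)
  x <- rnorm(300)
  y <- 1 + 0.8 * x + rnorm(300)
  f1 <- tidyCoef(fitLinear(y, data.frame(x = x)))
  f2 <- tidyCoef(fitLinear(y, data.frame(x = 10 * x)))
  expect_equal(f2$estimate[2], f1$estimate[2] / 10, tolerance = 1e-9)
  expect_equal(f2$statistic[2], f1$statistic[2], tolerance = 1e-9)
  yb <- rbinom(300, 1, plogis(0.5 * x))
  g1 <- tidyCoef(fitLogistic(yb, data.frame(x = x)))
  g2 <- tidyCoef(fitLogistic(yb, data.frame(x = 10 * x)))
  expect_equal(g2$statistic[2], g1$statistic[2], tolerance = 1e-6)
})

test_that("damage model fits the stated design in order b0..b5", {
  fl <- testFlock()
  fit <- damageModel(fl, "deviation_size", "linear", timepoint = "wk55")
  expect_identical(tidyCoef(fit)$term,
                   c("(Intercept)", "operatorB", "tibiotarsal", "keel",
                     "xlm", "bodyweight"))
  expect_s4_class(fit, "RegressionFit")
  expect_error(damageModel(fl, "not_a_column", "linear"), "missing")
  expect_error(damageModel(fl, "deviation_size", "censored_poisson"),
               "fracture count")
  # single-operator degenerate case drops the term
  fl1 <- fl
  fl1$operator <- "A"
  expect_warning(fit1 <- damageModel(fl1, "deviation_size", "linear"),
                 "single level")
  expect_false("operatorB" %in% tidyCoef(fit1)$term)
})

test_that("damage model recovers known coefficients from its own design", {
  fl <- testFlock()
  set.seed(65)
  b <- c(2, 0.5, -0.002, 0.01, 0.3, 0.0005)
  eta <- b[1] + b[2] * (fl$operator == "B") + b[3] * fl$tibio_wk55 +
    b[4] * fl$keeldens_wk55 + b[5] * fl$xlm_wk55 + b[6] * fl$bw_wk55
  fl$resp <- eta + rnorm(nrow(fl))
  cf <- tidyCoef(damageModel(fl, "resp", "linear", timepoint = "wk55"))
  expect_true(all(abs(cf$estimate - b) <= 2.6 * cf$se))
})

test_that("pelvic model validates capacity and reports the interaction", {
  fl <- testFlock()
  fits <- pelvicModel(fl, "keeldens_pmd", "all")
  expect_named(fits, c("width", "depth", "capacity"))
  cf <- tidyCoef(fits$capacity)
  expect_true("pelvic_x_tibiotarsal" %in% cf$term)
  bad <- fl
  bad$pelvic_capacity_mm2 <- bad$pelvic_capacity_mm2 + 5
  expect_error(pelvicModel(bad, "keeldens_pmd", "capacity"),
               "inconsistent")
})

test_that("pelvic model recovers a negative interaction by sign", {
  fl <- testFlock()
  ok <- 0
  for (i in 1:100) {
    set.seed(1200 + i)
    pel <- adjustForBodyweight(fl$pelvic_capacity_mm2, fl$bw_pm)
    eta <- 50 - 0.004 * scale(pel)[, 1] * fl$tibio_pmd
    fl$kd <- eta + rnorm(nrow(fl), sd = 2)
    cf <- tidyCoef(pelvicModel(fl, "kd", "capacity"))
    est <- cf$estimate[cf$term == "pelvic_x_tibiotarsal"]
    if (est < 0) ok <- ok + 1
  }
  expect_gte(ok / 100, 0.95)
})
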