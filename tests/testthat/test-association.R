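# Latent-normal correlations: closed forms, simulation oracles, invariances,
# Tukey letters and longitudinal matrices.

test_that("bivariate normal CDF reproduces closed forms", {
  expect_equal(bvnCdf(0, 0, 0), 0.25, tolerance = 1e-9)
  # orthant probability: 1/4 + asin(rho) / (2 pi)
  for (r in c(-0.7, -0.3, 0.5, 0.9)) {
    expect_equal(bvnCdf(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-7)
  }
  expect_equal(bvnCdf(Inf, Inf, 0.3), 1)
  expect_equal(bvnCdf(-Inf, 1, 0.3), 0)
  expect_equal(bvnCdf(Inf, 1.3, -0.5), pnorm(1.3), tolerance = 1e-9)
  # limits
  expect_equal(bvnCdf(0.5, 1, 1), pnorm(0.5))
  expect_equal(bvnCdf(0.5, 1, -1), pnorm(0.5) + pnorm(1) - 1)
  # agreement with the independent single-integral form
  for (r in c(-0.95, -0.4, 0.2, 0.8)) {
    expect_equal(bvnCdf(0.7, -1.2, r), oracleBvnCdf(0.7, -1.2, r),
                 tolerance = 1e-7)
  }
})

test_that("polychoric detects independence and perfect association", {
  # contingency structure with independent margins
  sim <- latentOrdinalPair(8000, 0, c(-0.5, 0.5), 0, seed = 31)
  est <- polychoric(sim$x, sim$y)
  expect_lt(abs(corRho(est)), 0.03)
  # perfectly concordant dichotomy -> boundary
  x <- rep(c(0, 1), each = 50)
  estB <- polychoric(x, x)
  expect_true(estB@boundary)
  expect_equal(corRho(estB), 0.9999)
  # degenerate margins rejected
  expect_error(polychoric(rep(1, 50), rep(c(0, 1), 25)), "2 observed")
})

test_that("polychoric recovers latent correlations from simulation", {
  sim <- latentOrdinalPair(10000, 0.5, c(-0.5, 0.5), 0, seed = 11)
  est <- polychoric(sim$x, sim$y)
  expect_lt(abs(corRho(est) - 0.5), 0.03)
  expect_equal(est@thresholdsX, c(-0.5, 0.5), tolerance = 0.1)
  # two-step cross-check lands close to the joint estimate
  est2 <- polychoric(sim$x, sim$y, twoStep = TRUE)
  expect_lt(abs(corRho(est2) - corRho(est)), 0.01)
})

test_that("polychoric SE tracks the replicate spread", {
  rhos <- numeric(200)
  ses <- numeric(200)
  for (i in 1:200) {
    sim <- latentOrdinalPair(1000, 0.4, c(-0.6, 0.5), c(-0.2, 0.9),
                             seed = 5000 + i)
    e <- polychoric(sim$x, sim$y)
    rhos[i] <- corRho(e)
    ses[i] <- corSe(e)
  }
  expect_lt(abs(mean(rhos) - 0.4), 0.02)
  expect_lt(abs(mean(ses) / sd(rhos) - 1), 0.25)
})

test_that("2x2 polychoric agrees with a grid-search tetrachoric oracle", {
  sim <- latentOrdinalPair(4000, 0.45, 0.2, -0.3, seed = 13)
  est <- polychoric(sim$x, sim$y)
  # oracle: thresholds at the margins, 1-D likelihood search over rho using
  # an independent CDF (single-integral form)
  tab <- table(sim$x, sim$y)
  h <- qnorm(sum(tab[1, ]) / sum(tab))
  k <- qnorm(sum(tab[, 1]) / sum(tab))
  negLL <- function(r) {
    p11 <- oracleBvnCdf(h, k, r)
    P <- matrix(c(p11, pnorm(k) - p11, pnorm(h) - p11,
                  1 - pnorm(h) - pnorm(k) + p11), 2, 2)
    -sum(tab * log(pmax(P, 1e-300)))
  }
  grid <- seq(-0.99, 0.99, by = 0.01)
  coarse <- grid[which.min(vapply(grid, negLL, 1))]
  fine <- seq(coarse - 0.02, coarse + 0.02, by = 1e-4)
  oracle <- fine[which.min(vapply(fine, negLL, 1))]
  expect_lt(abs(corRho(est) - oracle), 1e-3)
})

test_that("polychoric is symmetric and invariant to monotone relabeling", {
  sim <- latentOrdinalPair(3000, 0.35, c(-0.8, 0.4), c(0, 1), seed = 17)
  a <- polychoric(sim$x, sim$y)
  b <- polychoric(sim$y, sim$x)
  expect_equal(corRho(a), corRho(b), tolerance = 1e-5)
  # monotone relabeling 0,1,2 -> 10, 40, 41
  relab <- c(10, 40, 41)[sim$x + 1]
  c_ <- polychoric(relab, sim$y)
  expect_equal(corRho(c_), corRho(a), tolerance = 1e-8)
  expect_lte(abs(corRho(a)), 1)
})

test_that("polyserial recovers simulated mixed correlations", {
  set.seed(23)
  n <- 10000
  L <- chol(matrix(c(1, -0.88, -0.88, 1), 2))
  z <- matrix(rnorm(2 * n), ncol = 2) %*% L
  y <- findInterval(z[, 2], c(-0.6, 0.4))
  est <- polyserial(z[, 1], y)
  expect_lt(abs(corRho(est) - (-0.88)), 0.03)
  # affine rescaling of the continuous margin changes nothing
  est2 <- polyserial(100 + 7 * z[, 1], y)
  expect_equal(corRho(est2), corRho(est), tolerance = 1e-8)
  # independence
  estI <- polyserial(rnorm(n), findInterval(rnorm(n), c(-0.5, 0.5)))
  expect_lt(abs(corRho(estI)), 0.03)
})

test_that("polyserial hits the boundary under a deterministic link", {
  set.seed(29)
  x <- rnorm(2000)
  y <- as.integer(x > median(x))
  est <- polyserial(x, y)
  expect_true(est@boundary)
  expect_gt(corRho(est), 0.999)
})

test_that("pearson with SE reproduces the formula", {
  x <- c(1, 2, 3, 4, 5)
  est <- pearsonWithSe(x, 2 * x + 1)
  expect_equal(corRho(est), 1)
  expect_equal(corSe(est), 0)
  # se = sqrt((1 - r^2) / (n - 2)): r = 0 at n = 102 -> 0.1
  set.seed(5)
  est0 <- pearsonWithSe(rnorm(102), rnorm(102))
  expect_equal(corSe(est0), sqrt((1 - corRho(est0)^2) / 100))
  expect_error(pearsonWithSe(rep(1, 10), rnorm(10)), "variance")
  # simulation: mean r near 0.9
  rs <- replicate(300, {
    z <- matrix(rnorm(300), ncol = 2) %*%
      chol(matrix(c(1, 0.9, 0.9, 1), 2))
    corRho(pearsonWithSe(z[, 1], z[, 2]))
  })
  expect_lt(abs(mean(rs) - 0.9), 0.02)
})

test_that("Tukey letters: identical groups share, separated differ", {
  set.seed(41)
  g <- rep(c("a", "b", "c"), each = 30)
  same <- rnorm(90)
  tk <- groupMeansTukey(same, g)
  expect_true(all(tk$letters == tk$letters[1]))
  far <- rnorm(90, mean = rep(c(0, 10, 20), each = 30))
  tk2 <- groupMeansTukey(far, g)
  expect_equal(length(unique(tk2$letters)), 3)
})

test_that("two-group Tukey decision equals the pooled t-test", {
  for (s in 1:10) {
    set.seed(600 + s)
    y <- rnorm(40, mean = rep(c(0, 0.6), each = 20))
    g <- rep(c("a", "b"), each = 20)
    tk <- groupMeansTukey(y, g)
    tukeySig <- tk$letters[1] != tk$letters[2]
    tSig <- t.test(y ~ g, var.equal = TRUE)$p.value < 0.05
    expect_identical(tukeySig, tSig)
  }
})

test_that("singleton groups are excluded with a warning", {
  y <- c(rnorm(10), rnorm(10, 5), 3)
  g <- c(rep("a", 10), rep("b", 10), "c")
  expect_warning(tk <- groupMeansTukey(y, g), "singleton")
  expect_equal(sort(tk$group), c("a", "b"))
})

test_that("compact letters agree with multcomp on separated data", {
  set.seed(43)
  y <- rnorm(120, mean = rep(c(0, 0.2, 3, 3.1), each = 30))
  g <- factor(rep(c("g1", "g2", "g3", "g4"), each = 30))
  tk <- groupMeansTukey(y, g)
  fit <- stats::aov(y ~ g)
  cld <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(g = "Tukey")))
  # same partition: pairs sharing letters must match
  share <- function(lt, i, j) {
    any(strsplit(lt[i], "")[[1]] %in% strsplit(lt[j], "")[[1]])
  }
  ours <- tk$letters[match(levels(g), tk$group)]
  theirs <- cld$mcletters$Letters
  for (i in 1:3) for (j in (i + 1):4) {
    expect_identical(share(ours, i, j), share(theirs, i, j))
  }
})

test_that("longitudinal matrix reproduces AR(1) structure", {
  # persistent variable: all cells near 1
  n <- 300
  base <- rnorm(n)
  rec <- data.frame(bird_id = as.character(1:n))
  for (tp in c("wk16", "wk29", "wk42", "wk55", "wk68", "pm", "pmd")) {
    rec[[paste0("v_", tp)]] <- base + rnorm(n, sd = 1e-3)
  }
  m <- longitudinalMatrix(rec, "v")
  expect_true(all(m$rho > 0.999))
  expect_equal(nrow(m), choose(7, 2))
  # AR(1) with adjacent rho = 0.9: lag-2 cells near 0.81
  set.seed(47)
  z <- matrix(0, 2000, 7)
  z[, 1] <- rnorm(2000)
  for (t in 2:7) z[, t] <- 0.9 * z[, t - 1] + sqrt(1 - 0.81) * rnorm(2000)
  rec2 <- data.frame(bird_id = as.character(1:2000))
  tps <- c("wk16", "wk29", "wk42", "wk55", "wk68", "pm", "pmd")
  for (i in 1:7) rec2[[paste0("v_", tps[i])]] <- z[, i]
  m2 <- longitudinalMatrix(rec2, "v")
  adj <- m2[match(paste("wk29", "wk16"),
                  paste(m2$timepoint_a, m2$timepoint_b)), ]
  expect_equal(adj$rho, 0.9, tolerance = 0.05 / 0.9)
  lag2 <- m2[match(paste("wk42", "wk16"),
                   paste(m2$timepoint_a, m2$timepoint_b)), ]
  expect_equal(lag2$rho, 0.81, tolerance = 0.05 / 0.81)
  # white noise: all cells small
  rec3 <- rec2
  for (tp in tps) rec3[[paste0("v_", tp)]] <- rnorm(2000)
  m3 <- longitudinalMatrix(rec3, "v")
  expect_true(all(abs(m3$rho) < 0.15))
})
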