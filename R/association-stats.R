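# Latent-normal correlation machinery.
#
# Ordinal keel scores are modeled as discretizations of underlying standard
# normal variables: category k is observed when the latent value falls
# between thresholds tau_{k-1} and tau_k. The polychoric correlation is the
# latent correlation between two such variables, estimated by joint ML over
# (rho, thresholds) with multinomial cell probabilities given by rectangle
# probabilities of the standard bivariate normal. The polyserial case mixes
# one observed continuous margin with one ordinal margin.

RHO_CAP <- 0.9999

#' Standard bivariate normal CDF
#'
#' P(X <= h, Y <= k) for a standard bivariate normal with correlation rho.
#' Deterministic to ~1e-14 (TVPACK); limits at rho = +/-1 and infinite
#' bounds are handled explicitly.
#'
#' @param h,k upper integration bounds (may be +/-Inf).
#' @param rho correlation in [-1, 1].
#' @return probability.
#' @examples
#' bvnCdf(0, 0, 0)        # 0.25
#' bvnCdf(0, 0, 0.5)      # 1/4 + asin(0.5) / (2 * pi) = 1/3
#' @export
bvnCdf <- function(h, k, rho) {
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (rho >= 1 - 1e-12) return(stats::pnorm(min(h, k)))
  if (rho <= -1 + 1e-12) {
    return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  }
  if (is.infinite(h) && h < 0) return(0)
  if (is.infinite(k) && k < 0) return(0)
  if (is.infinite(h) && is.infinite(k)) return(1)
  if (is.infinite(h)) return(stats::pnorm(k))
  if (is.infinite(k)) return(stats::pnorm(h))
  as.numeric(mvtnorm::pmvnorm(
    upper = c(h, k),
    corr = matrix(c(1, rho, rho, 1), 2),
    algorithm = mvtnorm::TVPACK()))
}

# Rectangle probabilities of the contingency table under (rho, a, b):
# a, b are the finite threshold vectors of the two margins.
.polychoricCellProbs <- function(rho, a, b) {
  A <- c(-Inf, a, Inf)
  B <- c(-Inf, b, Inf)
  F <- matrix(0, length(A), length(B))
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      F[i, j] <- bvnCdf(A[i], B[j], rho)
    }
  }
  nr <- length(A) - 1
  nc <- length(B) - 1
  F[2:(nr + 1), 2:(nc + 1)] - F[1:nr, 2:(nc + 1)] -
    F[2:(nr + 1), 1:nc] + F[1:nr, 1:nc]
}

# thresholds <-> unconstrained parameterization (first value free, then
# log-increments) keeping them strictly increasing during optimization
.thrToPar <- function(t) {
  if (length(t) == 1) return(t)
  c(t[1], log(diff(t)))
}

.parToThr <- function(p) {
  if (length(p) == 1) return(unname(p))
  unname(p[1] + c(0, cumsum(exp(p[-1]))))
}

.marginThresholds <- function(counts) {
  cum <- cumsum(counts) / sum(counts)
  unname(stats::qnorm(cum[-length(cum)]))
}

#' Polychoric correlation (maximum likelihood)
#'
#' Latent-normal correlation between two ordinal variables, by joint ML over
#' the correlation and both threshold vectors (default), or with thresholds
#' fixed at their margin estimates (\code{twoStep = TRUE}, for
#' cross-checking). The standard error comes from the inverse observed
#' information, correlation diagonal. Estimates at the boundary are capped
#' at |rho| = 0.9999 and flagged.
#'
#' @param x,y ordinal vectors (integer codes or factors) of equal length
#'   >= 10, each with >= 2 observed categories.
#' @param twoStep estimate thresholds from the margins first, then rho alone.
#' @return a \linkS4class{CorrelationEstimate}.
#' @export
polychoric <- function(x, y, twoStep = FALSE) {
  keep <- !(is.na(x) | is.na(y))
  x <- factor(x[keep])
  y <- factor(y[keep])
  n <- length(x)
  if (n < 10) stop("polychoric needs at least 10 complete pairs")
  if (nlevels(x) < 2 || nlevels(y) < 2) {
    stop("each margin needs at least 2 observed categories")
  }
  tab <- table(x, y)
  a0 <- .marginThresholds(rowSums(tab))
  b0 <- .marginThresholds(colSums(tab))

  negLLRho <- function(rho, a, b) {
    P <- .polychoricCellProbs(rho, a, b)
    -sum(tab * log(pmax(P, 1e-300)))
  }
  rho1 <- stats::optimize(negLLRho, c(-RHO_CAP, RHO_CAP),
                          a = a0, b = b0)$minimum

  if (twoStep) {
    rhoHat <- rho1
    aHat <- a0
    bHat <- b0
    negLLz <- function(z) negLLRho(tanh(z), a0, b0)
    hess <- stats::optimHess(atanh(max(min(rhoHat, RHO_CAP), -RHO_CAP)),
                             negLLz)
    ll <- -negLLRho(rhoHat, aHat, bHat)
    seZ <- if (is.finite(hess[1]) && hess[1] > 0) 1 / sqrt(hess[1]) else NA
  } else {
    na <- length(a0)
    nb <- length(b0)
    par0 <- c(atanh(rho1), .thrToPar(a0), .thrToPar(b0))
    unpack <- function(par) {
      list(rho = tanh(par[1]),
           a = .parToThr(par[2:(1 + na)]),
           b = .parToThr(par[(2 + na):(1 + na + nb)]))
    }
    negLL <- function(par) {
      q <- unpack(par)
      negLLRho(q$rho, q$a, q$b)
    }
    opt <- stats::optim(par0, negLL, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    q <- unpack(opt$par)
    rhoHat <- q$rho
    aHat <- q$a
    bHat <- q$b
    ll <- -opt$value
    seZ <- tryCatch({
      hess <- stats::optimHess(opt$par, negLL)
      v <- solve(hess)[1, 1]
      if (is.finite(v) && v > 0) sqrt(v) else NA_real_
    }, error = function(e) NA_real_)
  }

  boundary <- abs(rhoHat) > RHO_CAP - 1e-6
  rhoOut <- max(min(rhoHat, RHO_CAP), -RHO_CAP)
  se <- if (boundary || is.na(seZ)) NA_real_ else (1 - rhoOut^2) * seZ
  est <- .CorrelationEstimate(rhoOut, se, "polychoric", n,
                              thresholdsX = aHat, thresholdsY = bHat,
                              boundary = boundary)
  attr(est, "logLik") <- ll
  est
}

#' Polyserial correlation (maximum likelihood)
#'
#' Latent-normal correlation between a continuous variable and an ordinal
#' variable. The continuous margin is standardized by its ML moments; the
#' likelihood multiplies the normal density of the continuous value by the
#' conditional probability of the observed ordinal interval under the
#' conditional normal. Joint ML over (rho, thresholds) by default.
#'
#' @param x continuous vector with nonzero variance.
#' @param y ordinal vector with >= 2 observed categories.
#' @param twoStep fix thresholds at their margin estimates.
#' @return a \linkS4class{CorrelationEstimate}.
#' @export
polyserial <- function(x, y, twoStep = FALSE) {
  keep <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[keep])
  y <- factor(y[keep])
  n <- length(x)
  if (n < 10) stop("polyserial needs at least 10 complete pairs")
  if (nlevels(y) < 2) stop("ordinal margin needs >= 2 observed categories")
  sdx <- sqrt(mean((x - mean(x))^2))
  if (sdx == 0) stop("continuous variable has zero variance")
  z <- (x - mean(x)) / sdx
  yi <- as.integer(y)
  t0 <- .marginThresholds(table(yi))

  negLLpar <- function(rho, tau) {
    s <- sqrt(1 - rho^2)
    tauPad <- c(-Inf, tau, Inf)
    hi <- (tauPad[yi + 1] - rho * z) / s
    lo <- (tauPad[yi] - rho * z) / s
    p <- pmax(stats::pnorm(hi) - stats::pnorm(lo), 1e-300)
    -sum(stats::dnorm(z, log = TRUE) + log(p))
  }
  rho1 <- stats::optimize(function(r) negLLpar(r, t0),
                          c(-RHO_CAP, RHO_CAP))$minimum

  if (twoStep) {
    rhoHat <- rho1
    tHat <- t0
    negLLz <- function(zz) negLLpar(tanh(zz), t0)
    hess <- stats::optimHess(atanh(max(min(rhoHat, RHO_CAP), -RHO_CAP)),
                             negLLz)
    ll <- -negLLpar(rhoHat, tHat)
    seZ <- if (is.finite(hess[1]) && hess[1] > 0) 1 / sqrt(hess[1]) else NA
  } else {
    nt <- length(t0)
    par0 <- c(atanh(rho1), .thrToPar(t0))
    negLL <- function(par) {
      negLLpar(tanh(par[1]), .parToThr(par[-1]))
    }
    opt <- stats::optim(par0, negLL, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    rhoHat <- tanh(opt$par[1])
    tHat <- .parToThr(opt$par[-1])
    ll <- -opt$value
    seZ <- tryCatch({
      hess <- stats::optimHess(opt$par, negLL)
      v <- solve(hess)[1, 1]
      if (is.finite(v) && v > 0) sqrt(v) else NA_real_
    }, error = function(e) NA_real_)
  }

  boundary <- abs(rhoHat) > RHO_CAP - 1e-6
  rhoOut <- max(min(rhoHat, RHO_CAP), -RHO_CAP)
  se <- if (boundary || is.na(seZ)) NA_real_ else (1 - rhoOut^2) * seZ
  est <- .CorrelationEstimate(rhoOut, se, "polyserial", n,
                              thresholdsY = tHat, boundary = boundary)
  attr(est, "logLik") <- ll
  est
}

#' Pearson correlation with standard error
#'
#' r with the large-sample standard error sqrt((1 - r^2) / (n - 2)), the
#' form used for the longitudinal correlation matrices.
#'
#' @param x,y numeric vectors; pairwise-complete observations are used.
#' @return a \linkS4class{CorrelationEstimate}.
#' @export
pearsonWithSe <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("pearsonWithSe needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the margins")
  }
  r <- stats::cor(x, y)
  se <- sqrt((1 - r^2) / (n - 2))
  .CorrelationEstimate(r, se, "pearson", n)
}

# Compact letter display by insert-and-absorb over the non-significance
# graph: groups sharing a letter are not significantly different.
.compactLetters <- function(groupNames, sigPairs, meansDesc) {
  g <- length(groupNames)
  cols <- list(rep(TRUE, g))
  for (p in sigPairs) {
    i <- p[1]
    j <- p[2]
    newCols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col
        c1[i] <- FALSE
        c2 <- col
        c2[j] <- FALSE
        newCols <- c(newCols, list(c1, c2))
      } else {
        newCols <- c(newCols, list(col))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(newCols))
    for (a in seq_along(newCols)) {
      for (b in seq_along(newCols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newCols[[a]] <= newCols[[b]]) &&
            any(newCols[[a]] < newCols[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    # drop exact duplicates
    sig <- vapply(newCols, function(cc) paste(as.integer(cc), collapse = ""),
                  character(1))
    keep <- keep & !duplicated(sig)
    cols <- newCols[keep]
  }
  ord <- order(vapply(cols, function(cc) min(match(which(cc), meansDesc)),
                      numeric(1)))
  cols <- cols[ord]
  letters_ <- letters[seq_along(cols)]
  out <- vapply(seq_len(g), function(i) {
    paste(letters_[vapply(cols, function(cc) cc[i], logical(1))],
          collapse = "")
  }, character(1))
  stats::setNames(out, groupNames)
}

#' Group means with Tukey HSD compact letters
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test at
#' the given level; groups sharing a letter do not differ significantly.
#' Singleton groups are excluded with a warning.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @param alpha significance level (default 0.05).
#' @return data.frame with group, n, mean, letters; attribute
#'   \code{tukey} holds the pairwise table.
#' @export
groupMeansTukey <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding singleton group(s): ", paste(drop, collapse = ", "))
    keep <- !(groups %in% drop)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with n >= 2")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  lev <- levels(groups)
  pairNames <- strsplit(rownames(tk), "-", fixed = TRUE)
  sigPairs <- list()
  for (i in seq_len(nrow(tk))) {
    if (tk[i, "p adj"] < alpha) {
      sigPairs <- c(sigPairs, list(match(pairNames[[i]], lev)))
    }
  }
  means <- tapply(values, groups, mean)
  meansDesc <- order(means, decreasing = TRUE)
  lets <- .compactLetters(lev, sigPairs, meansDesc)
  out <- data.frame(group = lev,
                    n = as.integer(table(groups)),
                    mean = as.numeric(means),
                    letters = unname(lets),
                    stringsAsFactors = FALSE)
  attr(out, "tukey") <- tk
  out
}

#' Longitudinal correlation matrix of one radiographic variable
#'
#' Pearson r with standard error for every pair of measurement occasions
#' (weeks 16 to 68, whole-body post-mortem PM, dissected-bone PMD),
#' pairwise-complete; cells with fewer than 3 complete pairs are empty.
#'
#' @param records wide per-bird data.frame with columns
#'   \code{<variable>_<timepoint>} (lowercase timepoint suffixes, e.g.
#'   \code{xlm_wk55}, \code{xlm_pmd}).
#' @param variable column prefix, e.g. \code{"tibio"}, \code{"keeldens"},
#'   \code{"xlm"}.
#' @param timepoints occasion codes to include, in order.
#' @return data.frame with timepoint_a, timepoint_b (a later than b), rho,
#'   se, n; lower-triangular layout.
#' @export
longitudinalMatrix <- function(records, variable, timepoints = TIMEPOINTS) {
  cols <- paste0(variable, "_", tolower(timepoints))
  miss <- setdiff(cols, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (i in seq_along(timepoints)[-1]) {
    for (j in seq_len(i - 1)) {
      xi <- records[[cols[i]]]
      xj <- records[[cols[j]]]
      ok <- is.finite(xi) & is.finite(xj)
      if (sum(ok) < 3) {
        row <- data.frame(timepoint_a = timepoints[i],
                          timepoint_b = timepoints[j],
                          rho = NA_real_, se = NA_real_, n = sum(ok))
      } else {
        est <- pearsonWithSe(xi, xj)
        row <- data.frame(timepoint_a = timepoints[i],
                          timepoint_b = timepoints[j],
                          rho = corRho(est), se = corSe(est), n = est@n)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
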