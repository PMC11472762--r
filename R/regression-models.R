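# Per-age damage regressions and pelvic-dimension interaction models.
#
# The damage model regresses a dissected-keel damage response on the
# operator plus the four radiographic predictors of one measurement
# occasion:
#   y = b0 + b1 operator + b2 tibiotarsal + b3 keel + b4 xlm
#       + b5 bodyweight + e
# fitted per age with a family matched to the response: linear for equally
# spaced ordinal scores, logistic for binary damage, right-censored Poisson
# for the fracture count (the top category is ">= four").
#
# The pelvic model adds the pelvic x tibiotarsal interaction:
#   y = b0 + b1 operator + b2 pelvic + b3 tibiotarsal
#       + b4 pelvic * tibiotarsal + e
# with pelvic dimensions residualized on body weight first (their
# correlation with body weight is ~0.65).

.regressionResult <- function(est, se, family, n, ll, resid, converged,
                              meta = list()) {
  stat <- est / se
  pv <- if (family == "linear") {
    2 * stats::pt(abs(stat), df = n - length(est), lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  }
  new("RegressionFit",
      coefficients = data.frame(term = names(est), estimate = unname(est),
                                se = unname(se), statistic = unname(stat),
                                p.value = unname(pv),
                                stringsAsFactors = FALSE),
      family = family, n = as.integer(n), logLik = ll,
      residuals = as.numeric(resid), converged = converged, meta = meta)
}

.designMatrix <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) == 0) {
    return(matrix(1, nrow(X), 1, dimnames = list(NULL, "(Intercept)")))
  }
  mm <- stats::model.matrix(~ ., data = X)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  mm
}

#' Ordinary least squares fit
#'
#' OLS with intercept, classical standard errors and t tests. Used for
#' responses on equally spaced ordinal scales and continuous responses.
#'
#' @param y numeric response.
#' @param X data.frame of predictors (an intercept is added; factors are
#'   dummy coded, reference = first level).
#' @return a \linkS4class{RegressionFit}.
#' @export
fitLinear <- function(y, X) {
  mm <- .designMatrix(X)
  if (length(y) <= ncol(mm)) stop("need n > number of parameters")
  fit <- stats::lm.fit(mm, y)
  est <- fit$coefficients
  n <- length(y)
  p <- ncol(mm)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(chol(crossprod(mm)))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- names(est)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  .regressionResult(est, se, "linear", n, ll, fit$residuals, TRUE)
}

#' Logistic regression fit
#'
#' ML logit fit with Wald standard errors. Perfect separation is flagged
#' (converged = FALSE, boundary warning) and the coefficients are still
#' reported.
#'
#' @param y binary response (0/1 or logical); both classes must be present.
#' @param X data.frame of predictors.
#' @return a \linkS4class{RegressionFit}.
#' @export
fitLogistic <- function(y, X) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("logistic response must be binary 0/1")
  if (length(unique(y)) < 2) stop("both response classes must be present")
  mm <- .designMatrix(X)
  fit <- suppressWarnings(
    stats::glm.fit(mm, y, family = stats::binomial()))
  est <- fit$coefficients
  separated <- any(fit$fitted.values > 1 - 1e-8 & y == 1) &&
    any(fit$fitted.values < 1e-8 & y == 0) ||
    any(abs(est) > 15)
  vc <- tryCatch(chol2inv(chol(crossprod(mm * sqrt(fit$weights)))),
                 error = function(e) matrix(NA, ncol(mm), ncol(mm)))
  se <- sqrt(diag(vc))
  names(se) <- names(est)
  if (separated) {
    warning("possible perfect separation: coefficients at the boundary")
  }
  ll <- sum(stats::dbinom(y, 1, pmin(pmax(fit$fitted.values, 1e-12),
                                     1 - 1e-12), log = TRUE))
  .regressionResult(est, se, "logistic", length(y), ll,
                    y - fit$fitted.values, !separated)
}

# Right-censored Poisson negative log-likelihood: uncensored observations
# contribute log Pois(y; lambda); censored ones ("y >= censorPoint")
# contribute log P(Y >= censorPoint; lambda).
.censPoisNegLL <- function(beta, mm, y, censored, censorPoint) {
  lam <- exp(pmin(mm %*% beta, 50))
  llU <- stats::dpois(y[!censored], lam[!censored], log = TRUE)
  llC <- stats::ppois(censorPoint - 1, lam[censored], lower.tail = FALSE,
                      log.p = TRUE)
  -(sum(llU) + sum(llC))
}

#' Right-censored Poisson regression
#'
#' ML Poisson regression with log link where counts recorded as "at or
#' above" the censor point contribute the upper-tail probability to the
#' likelihood. With no censored observations this is exactly Poisson
#' regression (intercept-only MLE = log of the sample mean). Wald standard
#' errors from the observed information.
#'
#' @param y non-negative integer counts (censored entries stored at the
#'   censor point).
#' @param censored logical flags; may be TRUE only where
#'   \code{y == censorPoint}.
#' @param X data.frame of predictors.
#' @param censorPoint the right-censoring cutoff (default 4, ">= four
#'   fractures").
#' @return a \linkS4class{RegressionFit}.
#' @export
fitCensoredPoisson <- function(y, censored, X, censorPoint = 4) {
  y <- as.numeric(y)
  censored <- as.logical(censored)
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  if (any(censored & y != censorPoint)) {
    stop("censored flags allowed only where y equals the censor point")
  }
  if (all(censored)) stop("all observations censored: model not identifiable")
  mm <- .designMatrix(X)
  start <- suppressWarnings(
    stats::glm.fit(mm, y, family = stats::poisson())$coefficients)
  opt <- stats::optim(start, .censPoisNegLL, mm = mm, y = y,
                      censored = censored, censorPoint = censorPoint,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  est <- opt$par
  names(est) <- colnames(mm)
  hess <- stats::optimHess(opt$par, .censPoisNegLL, mm = mm, y = y,
                           censored = censored, censorPoint = censorPoint)
  vc <- tryCatch(solve(hess), error = function(e) {
    matrix(NA, length(est), length(est))
  })
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(est)
  lam <- exp(as.numeric(mm %*% est))
  .regressionResult(est, se, "censored_poisson", length(y), -opt$value,
                    y - lam, opt$convergence == 0)
}

#' Adjust pelvic dimensions for body weight
#'
#' Residualizes a pelvic dimension on body weight by OLS and re-centers the
#' residuals at the original mean, removing the ~0.65 correlation with body
#' weight while preserving the scale.
#'
#' @param pelvic numeric pelvic dimension.
#' @param bodyweight numeric body weight of the same birds (n >= 10,
#'   non-constant).
#' @return adjusted values, same length and mean as \code{pelvic}.
#' @export
adjustForBodyweight <- function(pelvic, bodyweight) {
  if (length(pelvic) != length(bodyweight)) stop("lengths must match")
  if (length(pelvic) < 10) stop("need at least 10 observations")
  if (stats::sd(bodyweight) == 0) stop("body weight is constant")
  fit <- stats::lm(pelvic ~ bodyweight)
  as.numeric(stats::residuals(fit)) + mean(pelvic)
}

#' Validate pelvic dimensions
#'
#' Checks positivity and the capacity = width x depth invariant.
#'
#' @param records data.frame with pelvic_width_mm, pelvic_depth_mm and
#'   (optionally) pelvic_capacity_mm2.
#' @return the records with pelvic_capacity_mm2 filled in.
#' @export
validatePelvicDims <- function(records) {
  w <- records$pelvic_width_mm
  d <- records$pelvic_depth_mm
  if (is.null(w) || is.null(d)) {
    stop("records need pelvic_width_mm and pelvic_depth_mm")
  }
  if (any(w <= 0, na.rm = TRUE) || any(d <= 0, na.rm = TRUE)) {
    stop("pelvic dimensions must be positive")
  }
  cap <- w * d
  if (!is.null(records$pelvic_capacity_mm2)) {
    ok <- is.na(records$pelvic_capacity_mm2) |
      abs(records$pelvic_capacity_mm2 - cap) <=
        1e-6 * pmax(1, abs(cap))
    if (!all(ok)) {
      stop("pelvic_capacity_mm2 inconsistent with width x depth")
    }
  }
  records$pelvic_capacity_mm2 <- cap
  records
}

.tpCols <- function(timepoint) {
  tp <- tolower(timepoint)
  list(tibio = paste0("tibio_", tp), keel = paste0("keeldens_", tp),
       xlm = paste0("xlm_", tp), bw = paste0("bw_", tp))
}

#' Damage-on-radiography regression for one age
#'
#' Fits y = b0 + b1 operator + b2 tibiotarsal + b3 keel + b4 xlm
#' + b5 bodyweight + e for the requested timepoint, with the family matched
#' to the response. A single-level operator column is dropped with a
#' warning.
#'
#' @param records merged per-bird data.frame (see
#'   \code{\link{simulateFlock}} / \code{\link{mergeClean}} for the layout).
#' @param response response column, e.g. "deviation_size",
#'   "deviation_extent", "fracture_count", "damage_binary".
#' @param family "linear", "logistic" or "censored_poisson".
#' @param timepoint measurement occasion providing the radiographic
#'   predictors.
#' @param censorPoint censor point for the fracture count (default 4).
#' @return a \linkS4class{RegressionFit} with coefficients in the order
#'   b0 (intercept), b1 operator, b2 tibiotarsal, b3 keel, b4 xlm, b5 body
#'   weight.
#' @export
damageModel <- function(records, response,
                        family = c("linear", "logistic", "censored_poisson"),
                        timepoint = "wk68", censorPoint = 4) {
  family <- match.arg(family)
  if (family == "censored_poisson" && response != "fracture_count") {
    stop("censored_poisson is only valid for the fracture count response")
  }
  cols <- .tpCols(timepoint)
  need <- c(response, "operator", unlist(cols))
  if (response == "damage_binary" && !"damage_binary" %in% names(records)) {
    records$damage_binary <-
      as.integer(records$deviation_size > 0 | records$fracture_count > 0)
  }
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  }
  dat <- data.frame(
    y = records[[response]],
    operator = factor(records$operator),
    tibiotarsal = records[[cols$tibio]],
    keel = records[[cols$keel]],
    xlm = records[[cols$xlm]],
    bodyweight = records[[cols$bw]]
  )
  cens <- if (family == "censored_poisson") {
    if (!is.null(records$fracture_censored)) records$fracture_censored
    else rep(FALSE, nrow(dat))
  } else NULL
  ok <- stats::complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]
  if (!is.null(cens)) cens <- cens[ok]
  if (nlevels(droplevels(dat$operator)) < 2) {
    warning("operator has a single level; term dropped")
    dat$operator <- NULL
  } else {
    dat$operator <- droplevels(dat$operator)
  }
  X <- dat[, setdiff(names(dat), "y"), drop = FALSE]
  fit <- switch(family,
    linear = fitLinear(dat$y, X),
    logistic = fitLogistic(dat$y, X),
    censored_poisson = fitCensoredPoisson(dat$y, cens, X, censorPoint))
  fit@meta <- list(response = response, timepoint = timepoint,
                   family = family)
  fit
}

#' Keel-condition-on-pelvic-dimension regression
#'
#' Fits y = b0 + b1 operator + b2 pelvic + b3 tibiotarsal
#' + b4 pelvic * tibiotarsal + e, with the pelvic dimension residualized on
#' body weight first. With \code{pelvicVariable = "all"} the model is run
#' for pelvic width, depth and capacity and a named list is returned.
#'
#' @param records merged per-bird data.frame including pelvic_width_mm,
#'   pelvic_depth_mm, pelvic_capacity_mm2 and bw_pm.
#' @param response response column (e.g. "keeldens_pmd", "deviation_size",
#'   "keel_mid_depth_cm").
#' @param pelvicVariable "width", "depth", "capacity" or "all".
#' @param timepoint occasion providing the tibiotarsal predictor (default
#'   "pmd", the dissected-bone radiograph).
#' @param family regression family for the response.
#' @return a \linkS4class{RegressionFit}, or a named list of them for
#'   \code{"all"}.
#' @export
pelvicModel <- function(records, response,
                        pelvicVariable = c("capacity", "width", "depth",
                                           "all"),
                        timepoint = "pmd",
                        family = c("linear", "logistic",
                                   "censored_poisson")) {
  pelvicVariable <- match.arg(pelvicVariable)
  family <- match.arg(family)
  if (pelvicVariable == "all") {
    out <- lapply(c("width", "depth", "capacity"), function(v) {
      pelvicModel(records, response, v, timepoint, family)
    })
    names(out) <- c("width", "depth", "capacity")
    return(out)
  }
  records <- validatePelvicDims(records)
  pcol <- switch(pelvicVariable, width = "pelvic_width_mm",
                 depth = "pelvic_depth_mm", capacity = "pelvic_capacity_mm2")
  cols <- .tpCols(timepoint)
  need <- c(response, "operator", pcol, cols$tibio, "bw_pm")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  }
  dat <- data.frame(
    y = records[[response]],
    operator = factor(records$operator),
    pelvic = records[[pcol]],
    tibiotarsal = records[[cols$tibio]],
    bw = records$bw_pm
  )
  ok <- stats::complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]
  dat$pelvic <- adjustForBodyweight(dat$pelvic, dat$bw)
  if (nlevels(droplevels(dat$operator)) < 2) {
    warning("operator has a single level; term dropped")
    dat$operator <- NULL
  } else {
    dat$operator <- droplevels(dat$operator)
  }
  dat$pelvic_x_tibiotarsal <- dat$pelvic * dat$tibiotarsal
  X <- dat[, setdiff(names(dat), c("y", "bw")), drop = FALSE]
  cens <- rep(FALSE, nrow(dat))
  fit <- switch(family,
    linear = fitLinear(dat$y, X),
    logistic = fitLogistic(dat$y, X),
    censored_poisson = fitCensoredPoisson(dat$y, cens, X))
  fit@meta <- list(response = response, pelvic = pelvicVariable,
                   timepoint = timepoint, family = family)
  fit
}
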