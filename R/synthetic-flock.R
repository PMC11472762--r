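# Simulated flocks with the latent-normal structure the analysis assumes.
#
# One bird is one draw from a latent Gaussian system:
#   - a dissected block (deviation, fracture, callus liabilities + keel
#     length and mid-depth in cm) with the study's dissected-keel
#     correlation structure; ordinal scores arise by thresholding at the
#     study's printed marginal frequencies, the fracture count through a
#     Gaussian copula over a Poisson margin (right-censored at ">= four");
#   - extent scores drawn hierarchically given size (a correlated extent
#     liability, then a localization code of that extent), so the
#     localization -> extent recoding invariant holds by construction;
#   - radiographic anchors (keel density, tibiotarsal density, ratio) at the
#     dissected-bone occasion, correlated with the damage liability, then
#     propagated backwards through the measurement occasions with
#     nonstationary AR(1) adjacent correlations;
#   - pelvic width/depth correlated with final body weight, capacity =
#     width x depth.

.FLOCK_TP <- c("wk16", "wk29", "wk42", "wk55", "wk68", "pm", "pmd")

#' Flock simulation parameters
#'
#' Defaults encode the study conditions: marginal score frequencies, the
#' dissected-keel correlation structure, a Poisson fracture rate of 2
#' censored at 4, adjacent-age correlations of the three radiographic
#' variables, and a pelvic-dimension correlation of 0.65 with body weight.
#'
#' @param nBirds number of birds.
#' @param devSizeProbs,callusSizeProbs marginal category probabilities
#'   (sizes 0, 1, 2).
#' @param fracLambda Poisson fracture rate; \code{censorPoint} is the
#'   ">= four" category.
#' @param censorPoint right-censoring cutoff for the fracture count.
#' @param dissectedCorr 5 x 5 latent correlation matrix over (deviation,
#'   fracture, callus, keel length, keel mid-depth).
#' @param extentRho latent loading of the extent liability on the size
#'   liability, per damage type.
#' @param extentCondProbs per damage type, conditional extent probabilities
#'   (1, 2, 3 thirds) given damage present.
#' @param locWeights per damage type, sampling weights of the localization
#'   codes within extent 1 (codes 1..3) and extent 2 (codes 4..6).
#' @param lenMeanCm,lenSdCm,depMeanCm,depSdCm moments of dissected keel
#'   length and mid-depth.
#' @param radCorr 4 x 4 latent correlation matrix over (deviation liability,
#'   keel density anchor, tibiotarsal anchor, body weight).
#' @param xlmAnchorLoading loading of the radiographic ratio anchor on the
#'   (standardized) dissected length:mid-depth ratio.
#' @param adjCorr list of length-6 adjacent-occasion correlations
#'   (wk16-wk29, ..., pm-pmd) for tibio, keeldens and xlm.
#' @param tpMeans,tpSds per-occasion means and sds of the observed tibio,
#'   keeldens and xlm measurements (arbitrary units; the week-16 ratio is
#'   low because the keel is only partly ossified).
#' @param bwMeans,bwSd body-weight means (g) per live occasion + pm,
#'   and their sd.
#' @param bwLoading loading of each occasion's observed weight on the bird's
#'   weight latent.
#' @param pelvicBwCorr pelvic width/depth correlation with final body
#'   weight.
#' @param pelvicWidthMean,pelvicWidthSd,pelvicDepthMean,pelvicDepthSd pelvic
#'   dimension moments (mm).
#' @param pelvicWDCorr width-depth correlation.
#' @param fracBetaXlm log-linear effect of the ratio anchor on the fracture
#'   rate (0 by default; the copula already carries the association).
#' @param operatorProb probability of scorer "A".
#' @param layingProb probability of active-ovary laying status.
#' @return a validated parameter list of class \code{FlockSimParams}.
#' @export
flockParams <- function(
    nBirds = 155,
    devSizeProbs = c(0.25, 0.29, 0.46),
    callusSizeProbs = c(0.17, 0.41, 0.42),
    fracLambda = 2,
    censorPoint = 4,
    dissectedCorr = NULL,
    extentRho = c(deviation = 0.62, fracture = 0.65, callus = 0.50),
    extentCondProbs = list(
      deviation = c(0.30, 0.27, 0.19) / 0.76,
      fracture = c(0.72, 0.09, 0.05) / 0.86,
      callus = c(0.72, 0.10, 0.03) / 0.85),
    locWeights = list(
      deviation = list(e1 = c(0.09, 0.19, 0.02), e2 = c(0.17, 0.10, 0.01)),
      fracture = list(e1 = c(0.70, 0.01, 0.01), e2 = c(0.05, 0, 0.04)),
      callus = list(e1 = c(0.69, 0.01, 0.01), e2 = c(0.05, 0, 0.05))),
    lenMeanCm = 10.4, lenSdCm = 0.8, depMeanCm = 2, depSdCm = 0.28,
    radCorr = NULL,
    xlmAnchorLoading = 0.95,
    adjCorr = list(
      tibio = c(0.27, 0.13, 0.08, 0.26, 0.09, 0.06),
      keeldens = c(0.17, 0.81, 0.78, 0.78, 0.64, 0.63),
      xlm = c(-0.11, 0.29, 0.72, 0.90, 0.85, 0.66)),
    tpMeans = list(
      tibio = c(800, 1000, 1050, 1200, 1250, 1150, 1200),
      keeldens = c(60, 80, 95, 92, 90, 70, 72),
      xlm = c(3.5, 5.0, 5.2, 5.3, 5.3, 5.3, 5.3)),
    tpSds = list(
      tibio = rep(150, 7),
      keeldens = rep(12, 7),
      xlm = rep(0.75, 7)),
    bwMeans = c(1400, 1850, 1950, 2000, 2000, 2000),
    bwSd = 180,
    bwLoading = 0.9,
    pelvicBwCorr = 0.65,
    pelvicWidthMean = 40.43, pelvicWidthSd = 5.30,
    pelvicDepthMean = 71.92, pelvicDepthSd = 10.38,
    pelvicWDCorr = 0.51,
    fracBetaXlm = 0,
    operatorProb = 0.5,
    layingProb = 0.92) {
  if (is.null(dissectedCorr)) {
    v <- c("deviation", "fracture", "callus", "length", "middepth")
    dissectedCorr <- diag(5)
    dimnames(dissectedCorr) <- list(v, v)
    dissectedCorr["deviation", "fracture"] <- 0.34
    dissectedCorr["deviation", "callus"] <- 0.34
    dissectedCorr["deviation", "length"] <- 0.20
    dissectedCorr["deviation", "middepth"] <- -0.19
    dissectedCorr["fracture", "callus"] <- 0.79
    dissectedCorr["fracture", "length"] <- 0.08
    dissectedCorr["fracture", "middepth"] <- -0.33
    dissectedCorr["callus", "length"] <- 0.14
    dissectedCorr["callus", "middepth"] <- -0.14
    dissectedCorr["length", "middepth"] <- -0.11
    dissectedCorr[lower.tri(dissectedCorr)] <-
      t(dissectedCorr)[lower.tri(dissectedCorr)]
  }
  if (is.null(radCorr)) {
    v <- c("deviation", "keeldens", "tibio", "bw")
    radCorr <- diag(4)
    dimnames(radCorr) <- list(v, v)
    radCorr["deviation", "keeldens"] <- -0.20
    radCorr["deviation", "tibio"] <- -0.20
    radCorr["keeldens", "tibio"] <- 0.30
    radCorr[lower.tri(radCorr)] <- t(radCorr)[lower.tri(radCorr)]
  }
  p <- as.list(environment())
  for (m in list(p$dissectedCorr, p$radCorr)) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("correlation matrix is not positive definite")
  }
  stopifnot(abs(sum(devSizeProbs) - 1) < 1e-9,
            abs(sum(callusSizeProbs) - 1) < 1e-9,
            all(vapply(adjCorr, length, 1L) == 6),
            all(unlist(adjCorr) > -1 & unlist(adjCorr) < 1))
  class(p) <- "FlockSimParams"
  p
}

# Hierarchical extent + localization given the size/count and the primary
# latent: extent liability = rho * primary + sqrt(1 - rho^2) * noise,
# thresholded at the conditional probabilities; a localization code of that
# extent is then drawn from the within-extent weights.
.drawExtentLoc <- function(present, zPrimary, rho, condProbs, weights) {
  n <- length(present)
  extent <- integer(n)
  loc <- integer(n)
  idx <- which(present)
  if (length(idx)) {
    zExt <- rho * zPrimary[idx] +
      sqrt(1 - rho^2) * stats::rnorm(length(idx))
    thr <- stats::qnorm(cumsum(condProbs))[1:2]
    e <- 1L + findInterval(zExt, thr)
    locSub <- integer(length(idx))
    locSub[e == 3] <- 7L
    if (any(e == 1)) {
      locSub[e == 1] <- sample(1:3, sum(e == 1), replace = TRUE,
                               prob = weights$e1)
    }
    if (any(e == 2)) {
      locSub[e == 2] <- sample(4:6, sum(e == 2), replace = TRUE,
                               prob = weights$e2)
    }
    extent[idx] <- e
    loc[idx] <- locSub
  }
  list(extent = extent, loc = loc)
}

#' Simulate a flock
#'
#' Draws per-bird latent normals and produces the merged wide record the
#' pipeline consumes: dissected keel scores with extents and localizations,
#' censored fracture counts, dissected keel length/mid-depth, longitudinal
#' radiographic measurements at weeks 16-68 plus whole-body (pm) and
#' dissected-bone (pmd) post-mortem occasions, body weights, pelvic
#' dimensions and operator labels. A fixed seed gives identical output.
#'
#' @param params a \code{\link{flockParams}} list.
#' @param seed RNG seed.
#' @param nBirds optional override of \code{params$nBirds}.
#' @return data.frame, one row per bird; attribute \code{params} carries the
#'   generating parameters.
#' @export
simulateFlock <- function(params = flockParams(), seed = 1,
                          nBirds = NULL) {
  stopifnot(inherits(params, "FlockSimParams"))
  set.seed(seed)
  n <- if (is.null(nBirds)) params$nBirds else nBirds

  # dissected latent block
  zd <- rmvnormChol(n, params$dissectedCorr)
  colnames(zd) <- colnames(params$dissectedCorr)
  lenCm <- params$lenMeanCm + params$lenSdCm * zd[, "length"]
  depCm <- params$depMeanCm + params$depSdCm * zd[, "middepth"]
  depCm <- pmax(depCm, 0.3)
  xlmDiss <- lenCm / depCm

  devThr <- stats::qnorm(cumsum(params$devSizeProbs))[1:2]
  devSize <- findInterval(zd[, "deviation"], devThr)
  calThr <- stats::qnorm(cumsum(params$callusSizeProbs))[1:2]
  calSize <- findInterval(zd[, "callus"], calThr)

  lam <- params$fracLambda *
    exp(params$fracBetaXlm * scale(xlmDiss)[, 1])
  # Gaussian copula over a Poisson margin: latent correlations carry over
  fracLatent <- stats::qpois(stats::pnorm(zd[, "fracture"]), lam)
  fracCensored <- fracLatent >= params$censorPoint
  fracCount <- pmin(fracLatent, params$censorPoint)

  dev <- .drawExtentLoc(devSize > 0, zd[, "deviation"],
                        params$extentRho[["deviation"]],
                        params$extentCondProbs$deviation,
                        params$locWeights$deviation)
  frc <- .drawExtentLoc(fracCount > 0, zd[, "fracture"],
                        params$extentRho[["fracture"]],
                        params$extentCondProbs$fracture,
                        params$locWeights$fracture)
  cal <- .drawExtentLoc(calSize > 0, zd[, "callus"],
                        params$extentRho[["callus"]],
                        params$extentCondProbs$callus,
                        params$locWeights$callus)

  # radiographic + body-weight anchors conditional on the deviation latent
  za <- rmvnormChol(n, params$radCorr, given = zd[, "deviation"])
  colnames(za) <- colnames(params$radCorr)
  zBw <- za[, "bw"]

  # observed body weights per occasion (wk16..wk68, pm)
  bwTp <- c("wk16", "wk29", "wk42", "wk55", "wk68", "pm")
  bw <- sapply(seq_along(bwTp), function(i) {
    zi <- params$bwLoading * zBw +
      sqrt(1 - params$bwLoading^2) * stats::rnorm(n)
    params$bwMeans[i] + params$bwSd * zi
  })
  colnames(bw) <- paste0("bw_", bwTp)
  zBwPm <- (bw[, "bw_pm"] - params$bwMeans[6]) / params$bwSd

  # pelvic dimensions correlated with the observed final weight
  r <- params$pelvicBwCorr
  resCorr <- (params$pelvicWDCorr - r^2) / (1 - r^2)
  if (abs(resCorr) >= 1) stop("pelvic width-depth correlation infeasible")
  e <- rmvnormChol(n, matrix(c(1, resCorr, resCorr, 1), 2))
  zPw <- r * zBwPm + sqrt(1 - r^2) * e[, 1]
  zPd <- r * zBwPm + sqrt(1 - r^2) * e[, 2]
  pw <- params$pelvicWidthMean + params$pelvicWidthSd * zPw
  pd <- params$pelvicDepthMean + params$pelvicDepthSd * zPd

  # longitudinal chains, anchored at the dissected-bone occasion and
  # propagated backwards with the adjacent correlations
  anchors <- list(
    tibio = za[, "tibio"],
    keeldens = za[, "keeldens"],
    xlm = params$xlmAnchorLoading * scale(xlmDiss)[, 1] +
      sqrt(1 - params$xlmAnchorLoading^2) * stats::rnorm(n))
  meas <- list()
  for (v in names(anchors)) {
    z <- matrix(0, n, 7)
    z[, 7] <- anchors[[v]]
    rhoAdj <- params$adjCorr[[v]]
    for (t in 6:1) {
      z[, t] <- rhoAdj[t] * z[, t + 1] +
        sqrt(1 - rhoAdj[t]^2) * stats::rnorm(n)
    }
    obs <- sweep(sweep(z, 2, params$tpSds[[v]], "*"), 2,
                 params$tpMeans[[v]], "+")
    colnames(obs) <- paste0(v, "_", .FLOCK_TP)
    meas[[v]] <- obs
  }

  out <- data.frame(
    bird_id = sprintf("B%04d", seq_len(n)),
    operator = ifelse(stats::runif(n) < params$operatorProb, "A", "B"),
    laying_status = stats::runif(n) < params$layingProb,
    deviation_size = devSize,
    deviation_loc = dev$loc,
    deviation_extent = dev$extent,
    fracture_count = fracCount,
    fracture_censored = fracCensored,
    fracture_loc = frc$loc,
    fracture_extent = frc$extent,
    callus_size = calSize,
    callus_loc = cal$loc,
    callus_extent = cal$extent,
    keel_length_cm = lenCm,
    keel_mid_depth_cm = depCm,
    xlm_dissected = xlmDiss,
    pelvic_width_mm = pw,
    pelvic_depth_mm = pd,
    pelvic_capacity_mm2 = pw * pd,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(bw))
  out$bw_pmd <- out$bw_pm  # dissected bones share the final weighing
  for (v in names(meas)) out <- cbind(out, as.data.frame(meas[[v]]))
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' Write a combined flock sheet
#'
#' Writes the merged per-bird record in the combined-data-sheet layout the
#' pipeline ingests (CSV). Optionally corrupts a fraction of rows (blank id
#' or missing values) to exercise the cleaning stage; the returned object
#' records which rows stayed intact.
#'
#' @param records flock data.frame (from \code{\link{simulateFlock}} or
#'   real data in the same layout).
#' @param path output CSV path.
#' @param missingRate fraction of rows to corrupt (0 = none).
#' @param seed RNG seed for the corruption draw.
#' @return invisibly, list with \code{path} and \code{intact_ids} (bird ids
#'   left untouched).
#' @export
writeFlockSheet <- function(records, path, missingRate = 0, seed = 1) {
  records <- as.data.frame(records)
  intact <- records$bird_id
  if (missingRate > 0) {
    set.seed(seed)
    nBad <- ceiling(missingRate * nrow(records))
    bad <- sample(nrow(records), nBad)
    numCols <- c("deviation_size", "fracture_count", "keel_length_cm",
                 "xlm_wk55", "tibio_wk68", "pelvic_width_mm")
    numCols <- intersect(numCols, names(records))
    for (i in bad) {
      if (stats::runif(1) < 0.3) {
        records$bird_id[i] <- ""
      } else {
        col <- sample(numCols, 1)
        records[i, col] <- NA
      }
    }
    intact <- records$bird_id[setdiff(seq_len(nrow(records)), bad)]
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(list(path = path, intact_ids = intact))
}

#' Read a combined flock sheet
#'
#' @param path CSV path written by \code{\link{writeFlockSheet}} (or real
#'   data in the same layout).
#' @return data.frame with blank bird ids mapped to NA.
#' @export
readFlockSheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("bird_id" %in% names(df)) {
    df$bird_id[!is.na(df$bird_id) & df$bird_id == ""] <- NA
  }
  df
}
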