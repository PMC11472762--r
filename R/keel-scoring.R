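# Dissected-keel damage scoring: localization codes, extent recoding and
# frequency / co-frequency tabulation.
#
# The keel is divided into three parts (cranial, middle, caudal). Damage
# localization is recorded as a code 0..7 naming the affected parts:
#   0 none, 1 caudal, 2 middle, 3 cranial, 4 caudal+middle,
#   5 middle+cranial, 6 caudal+cranial, 7 all three.
# The extent score 0..3 is the number of affected thirds.

.LOC_EXTENT <- c(`0` = 0L, `1` = 1L, `2` = 1L, `3` = 1L,
                 `4` = 2L, `5` = 2L, `6` = 2L, `7` = 3L)

SCORE_VARIABLES <- c("deviation_size", "deviation_loc", "deviation_extent",
                     "fracture_count", "fracture_loc", "fracture_extent",
                     "callus_size", "callus_loc", "callus_extent")

.SCORE_LEVELS <- list(
  deviation_size = 0:2, deviation_loc = 0:7, deviation_extent = 0:3,
  fracture_count = 0:4, fracture_loc = 0:7, fracture_extent = 0:3,
  callus_size = 0:2, callus_loc = 0:7, callus_extent = 0:3
)

#' Recode damage localization to extent
#'
#' Maps a localization code (which thirds of the keel are affected) to the
#' extent score: the number of affected thirds (1 for damage on one third, 2
#' for damage extending to two thirds, 3 for damage over all keel parts).
#'
#' @param loc integer vector of localization codes in 0..7.
#' @return integer vector of extent scores in 0..3.
#' @examples
#' localizationToExtent(0:7)
#' @export
localizationToExtent <- function(loc) {
  loc <- as.integer(loc)
  if (any(is.na(loc)) || any(loc < 0L | loc > 7L)) {
    stop("localization codes must be integers in 0..7")
  }
  unname(.LOC_EXTENT[as.character(loc)])
}

#' Validate a dissected-keel score table
#'
#' Checks the scoring-protocol invariants on a per-bird score data.frame:
#' categories in range, localization 0 exactly when the size/count is 0,
#' extent equal to the localization recoding, and the censored flag only on
#' the "at least four fractures" category.
#'
#' @param scores data.frame with columns bird_id, operator, deviation_size,
#'   deviation_loc, fracture_count, fracture_censored, fracture_loc,
#'   callus_size, callus_loc and (optionally, else derived) the three extent
#'   columns, keel_length_cm, keel_mid_depth_cm, laying_status.
#' @return the validated data.frame with extent columns filled in.
#' @export
validateKeelScores <- function(scores) {
  need <- c("bird_id", "deviation_size", "deviation_loc", "fracture_count",
            "fracture_loc", "callus_size", "callus_loc")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    stop("score table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(scores$bird_id)) {
    stop("duplicate bird_id in score table")
  }
  chk <- function(x, lo, hi, nm) {
    if (any(is.na(x)) || any(x < lo | x > hi)) {
      stop(sprintf("%s must lie in %d..%d", nm, lo, hi))
    }
  }
  chk(scores$deviation_size, 0, 2, "deviation_size")
  chk(scores$callus_size, 0, 2, "callus_size")
  chk(scores$fracture_count, 0, 4, "fracture_count")
  for (v in c("deviation", "fracture", "callus")) {
    sizeCol <- if (v == "fracture") "fracture_count" else paste0(v, "_size")
    loc <- scores[[paste0(v, "_loc")]]
    chk(loc, 0, 7, paste0(v, "_loc"))
    present <- scores[[sizeCol]] > 0
    if (any(present != (loc > 0))) {
      stop(sprintf("%s_loc must be 0 exactly when %s is 0", v, sizeCol))
    }
    extCol <- paste0(v, "_extent")
    ext <- localizationToExtent(loc)
    if (extCol %in% names(scores)) {
      if (any(scores[[extCol]] != ext)) {
        stop(extCol, " inconsistent with ", v, "_loc recoding")
      }
    }
    scores[[extCol]] <- ext
  }
  if ("fracture_censored" %in% names(scores)) {
    bad <- scores$fracture_censored & scores$fracture_count != 4
    if (any(bad)) stop("fracture_censored flag only allowed when count = 4")
  } else {
    scores$fracture_censored <- FALSE
  }
  scores
}

#' Per-category frequency of a keel score variable
#'
#' Proportions over all birds, reporting every protocol category even when
#' empty; proportions sum to 1.
#'
#' @param scores score data.frame (see \code{\link{validateKeelScores}}).
#' @param variable one of the scoring variables, e.g. "deviation_size".
#' @return named numeric vector of proportions, names = category codes.
#' @export
frequencyTable <- function(scores, variable) {
  if (!variable %in% SCORE_VARIABLES) {
    stop("unknown score variable '", variable, "'; valid: ",
         paste(SCORE_VARIABLES, collapse = ", "))
  }
  x <- scores[[variable]]
  if (is.null(x) || length(x) == 0) stop("no observations for ", variable)
  lev <- .SCORE_LEVELS[[variable]]
  counts <- table(factor(x, levels = lev))
  stats::setNames(as.numeric(counts) / length(x), as.character(lev))
}

.damageFlag <- function(scores, variable) {
  col <- switch(variable,
    deviation = "deviation_size",
    fracture = "fracture_count",
    callus = "callus_size",
    stop("unknown damage variable '", variable,
         "'; valid: deviation, fracture, callus"))
  scores[[col]] > 0
}

#' Co-frequency of two damage types
#'
#' Proportion of birds showing both damage types, where "damage" means
#' size/count > 0. \code{coFrequency(x, x)} equals the prevalence of x.
#'
#' @param scores score data.frame.
#' @param a,b damage variables: "deviation", "fracture" or "callus".
#' @return numeric proportion in [0, 1].
#' @export
coFrequency <- function(scores, a, b) {
  mean(.damageFlag(scores, a) & .damageFlag(scores, b))
}

#' Prevalence of a damage type, and of any keel damage
#'
#' \code{damagePrevalence(scores)} with the default \code{variable = "any"}
#' returns the headline prevalence: the proportion of keels with a deviation
#' or a fracture (callus is tabulated separately).
#'
#' @param scores score data.frame.
#' @param variable "deviation", "fracture", "callus" or "any".
#' @return numeric proportion in [0, 1].
#' @export
damagePrevalence <- function(scores, variable = "any") {
  if (variable == "any") {
    return(mean(.damageFlag(scores, "deviation") |
                  .damageFlag(scores, "fracture")))
  }
  mean(.damageFlag(scores, variable))
}
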