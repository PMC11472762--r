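# Orchestration: merge + clean per-bird records and emit the result bundle
# (frequencies, correlation matrices, group comparisons, regression
# summaries) as CSV files plus a run manifest.

.TABLE3_VARS <- c("deviation_size", "deviation_extent", "fracture_count",
                  "fracture_extent", "callus_size", "callus_extent",
                  "keel_length_cm", "keel_mid_depth_cm", "xlm_dissected")
.TABLE3_CONTINUOUS <- c("keel_length_cm", "keel_mid_depth_cm",
                        "xlm_dissected")

#' Merge and clean the per-bird data sources
#'
#' Inner-joins radiographic measurements, dissected keel scores and pelvic
#' dimensions on bird id, then excludes birds with a missing/blank id or a
#' missing value in any required column. Every exclusion is logged with its
#' reason.
#'
#' @param measurements data.frame keyed by bird_id (wide radiographic
#'   measurements).
#' @param scores data.frame keyed by bird_id (dissected keel scores).
#' @param pelvic data.frame keyed by bird_id (pelvic dimensions + body
#'   weight), or NULL when already merged into \code{scores}.
#' @param required columns that must be complete; default: every column of
#'   the merged table.
#' @return list with \code{records} (clean merged data.frame) and
#'   \code{exclusions} (data.frame bird_id, reason).
#' @export
mergeClean <- function(measurements, scores, pelvic = NULL,
                       required = NULL) {
  sources <- list(measurements = measurements, scores = scores)
  if (!is.null(pelvic)) sources$pelvic <- pelvic
  for (nm in names(sources)) {
    src <- sources[[nm]]
    if (!"bird_id" %in% names(src)) stop(nm, " lacks a bird_id column")
    ids <- src$bird_id[!is.na(src$bird_id) & src$bird_id != ""]
    if (anyDuplicated(ids)) {
      stop("duplicate bird_id within source '", nm, "'")
    }
  }
  exclusions <- data.frame(bird_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  merged <- sources[[1]]
  for (nm in names(sources)[-1]) {
    merged <- merge(merged, sources[[nm]], by = "bird_id")
  }
  badId <- is.na(merged$bird_id) | merged$bird_id == ""
  if (any(badId)) {
    exclusions <- rbind(exclusions,
                        data.frame(bird_id = "<blank>",
                                   reason = "missing bird id"))
    merged <- merged[!badId, , drop = FALSE]
  }
  for (nm in names(sources)) {
    ids <- sources[[nm]]$bird_id
    ids <- ids[!is.na(ids) & ids != ""]
    lost <- setdiff(ids, merged$bird_id)
    if (length(lost)) {
      exclusions <- rbind(exclusions,
        data.frame(bird_id = lost,
                   reason = paste0("absent from other source(s)")))
    }
  }
  if (is.null(required)) required <- setdiff(names(merged), "bird_id")
  required <- intersect(required, names(merged))
  for (i in rev(seq_len(nrow(merged)))) {
    row <- merged[i, required, drop = FALSE]
    missCol <- names(row)[vapply(row, function(v) is.na(v)[1], logical(1))]
    if (length(missCol)) {
      exclusions <- rbind(exclusions,
        data.frame(bird_id = merged$bird_id[i],
                   reason = paste0("missing ", missCol[1])))
      merged <- merged[-i, , drop = FALSE]
    }
  }
  rownames(merged) <- NULL
  list(records = merged, exclusions = exclusions)
}

# Clean a single already-merged sheet: drop blank ids and rows with NA in
# the required columns, logging reasons.
.cleanSheet <- function(records, required = NULL) {
  scores <- records
  scores$bird_id[!is.na(scores$bird_id) & scores$bird_id == ""] <- NA
  exclusions <- data.frame(bird_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  bad <- is.na(scores$bird_id)
  if (any(bad)) {
    exclusions <- rbind(exclusions,
      data.frame(bird_id = rep("<blank>", sum(bad)),
                 reason = "missing bird id"))
    scores <- scores[!bad, , drop = FALSE]
  }
  if (anyDuplicated(scores$bird_id)) stop("duplicate bird_id in sheet")
  if (is.null(required)) required <- setdiff(names(scores), "bird_id")
  required <- intersect(required, names(scores))
  cc <- stats::complete.cases(scores[, required, drop = FALSE])
  if (any(!cc)) {
    for (i in which(!cc)) {
      missCol <- required[is.na(scores[i, required])][1]
      exclusions <- rbind(exclusions,
        data.frame(bird_id = scores$bird_id[i],
                   reason = paste0("missing ", missCol)))
    }
    scores <- scores[cc, , drop = FALSE]
  }
  rownames(scores) <- NULL
  list(records = scores, exclusions = exclusions)
}

# Dissected-keel association matrix: polychoric for two ordinal margins,
# polyserial for mixed, Pearson for two continuous margins.
.table3Matrix <- function(records, vars = .TABLE3_VARS) {
  out <- list()
  for (i in seq_along(vars)[-1]) {
    for (j in seq_len(i - 1)) {
      a <- vars[i]
      b <- vars[j]
      contA <- a %in% .TABLE3_CONTINUOUS
      contB <- b %in% .TABLE3_CONTINUOUS
      est <- tryCatch({
        if (contA && contB) {
          pearsonWithSe(records[[a]], records[[b]])
        } else if (contA) {
          polyserial(records[[a]], records[[b]])
        } else if (contB) {
          polyserial(records[[b]], records[[a]])
        } else {
          polychoric(records[[a]], records[[b]])
        }
      }, error = function(e) NULL)
      out[[length(out) + 1]] <- data.frame(
        var_a = a, var_b = b,
        method = if (is.null(est)) NA_character_ else est@method,
        rho = if (is.null(est)) NA_real_ else corRho(est),
        se = if (is.null(est)) NA_real_ else corSe(est),
        n = if (is.null(est)) NA_integer_ else est@n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.defaultDamageSpecs <- function() {
  list(
    list(response = "deviation_size", family = "linear"),
    list(response = "deviation_extent", family = "linear"),
    list(response = "fracture_count", family = "censored_poisson"),
    list(response = "damage_binary", family = "logistic"))
}

#' Measure a directory of radiographs against a sidecar annotation file
#'
#' Every annotation is matched to an image file whose base name equals its
#' image_id; annotations referencing a missing image are skipped with a
#' warning. Bird id and timepoint are parsed from image ids of the form
#' \code{<bird>_<timepoint>} when possible.
#'
#' @param imageDir directory containing DICOM/PNG/TIFF radiographs.
#' @param annotationPath sidecar JSON (see \code{\link{loadAnnotations}}).
#' @param fallbackMmPerPx spacing used for files that carry none.
#' @return data.frame of morphometric records, one row per measured image.
#' @export
measureImages <- function(imageDir, annotationPath, fallbackMmPerPx = NA) {
  anns <- loadAnnotations(annotationPath)
  files <- list.files(imageDir, full.names = TRUE)
  ids <- tools::file_path_sans_ext(basename(files))
  rows <- list()
  for (ann in anns) {
    hit <- which(ids == imageId(ann))
    if (!length(hit)) {
      warning("no image found for annotation '", imageId(ann),
              "'; skipped")
      next
    }
    parts <- strsplit(imageId(ann), "_", fixed = TRUE)[[1]]
    tp <- if (length(parts) >= 2 &&
                parts[length(parts)] %in% TIMEPOINTS) {
      parts[length(parts)]
    } else NA
    bird <- if (!is.na(tp)) {
      paste(parts[-length(parts)], collapse = "_")
    } else imageId(ann)
    img <- loadRadiograph(files[hit[1]], fallbackMmPerPx = fallbackMmPerPx,
                          birdId = bird, timepoint = tp)
    rows[[length(rows) + 1]] <-
      measureRadiograph(img, ann, fallbackMmPerPx = fallbackMmPerPx)
  }
  if (!length(rows)) {
    return(data.frame())
  }
  do.call(rbind, rows)
}

#' Run the full analysis bundle
#'
#' Ingests a combined per-bird sheet (path or data.frame), cleans it, and
#' writes the result tables: score frequencies, damage co-frequencies and
#' prevalences, the dissected-keel correlation matrix
#' (polychoric/polyserial/Pearson), longitudinal correlation matrices of the
#' three radiographic variables, group means of the dissected length to
#' mid-depth ratio with Tukey letters, per-age damage-model coefficient
#' tables and pelvic-model coefficient tables, plus a run manifest. Any
#' stage failure aborts with the stage name and removes partial outputs.
#'
#' @param config list with elements: \code{data} (data.frame) or
#'   \code{input} (CSV path); \code{outdir} output directory; optional
#'   \code{seed} recorded in the manifest; optional \code{damageSpecs}
#'   (list of \code{list(response =, family =)}), \code{pelvicResponses},
#'   \code{timepoints}, \code{required} (columns that must be complete
#'   during cleaning).
#' @return invisibly, a list with all result tables and the exclusion log.
#' @export
runAll <- function(config) {
  if (is.null(config$outdir)) stop("config$outdir is required")
  records <- if (!is.null(config$data)) as.data.frame(config$data)
             else if (!is.null(config$input)) readFlockSheet(config$input)
             else stop("config needs 'data' or 'input'")
  damageSpecs <- if (is.null(config$damageSpecs)) .defaultDamageSpecs()
                 else config$damageSpecs
  pelvicResponses <- if (is.null(config$pelvicResponses)) {
    c("keeldens_pmd", "deviation_size", "keel_mid_depth_cm")
  } else config$pelvicResponses
  timepoints <- if (is.null(config$timepoints)) TIMEPOINTS
                else config$timepoints

  # validate requested names before any computation
  known <- c(names(records), "damage_binary")
  for (spec in damageSpecs) {
    if (!spec$response %in% known) {
      stop("unknown response name '", spec$response, "'")
    }
  }
  if (!all(pelvicResponses %in% known)) {
    stop("unknown response name '",
         setdiff(pelvicResponses, known)[1], "'")
  }
  if (!all(timepoints %in% TIMEPOINTS)) {
    stop("unknown timepoint '", setdiff(timepoints, TIMEPOINTS)[1], "'")
  }

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, file) {
    path <- file.path(config$outdir, file)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  results <- list()

  cleaned <- stage("clean", {
    out <- .cleanSheet(records, required = config$required)
    out$records <- validateKeelScores(out$records)
    out
  })
  rec <- cleaned$records
  results$exclusions <- cleaned$exclusions
  if (!"damage_binary" %in% names(rec)) {
    rec$damage_binary <- as.integer(rec$deviation_size > 0 |
                                      rec$fracture_count > 0)
  }

  results$frequencies <- stage("frequencies", {
    rows <- lapply(SCORE_VARIABLES, function(v) {
      p <- frequencyTable(rec, v)
      data.frame(variable = v, category = names(p),
                 proportion = as.numeric(p), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  results$cofrequencies <- stage("cofrequencies", {
    data.frame(
      measure = c("prevalence_any_damage", "prevalence_deviation",
                  "prevalence_fracture", "prevalence_callus",
                  "cofrequency_deviation_fracture",
                  "cofrequency_fracture_callus",
                  "cofrequency_deviation_callus"),
      proportion = c(damagePrevalence(rec),
                     damagePrevalence(rec, "deviation"),
                     damagePrevalence(rec, "fracture"),
                     damagePrevalence(rec, "callus"),
                     coFrequency(rec, "deviation", "fracture"),
                     coFrequency(rec, "fracture", "callus"),
                     coFrequency(rec, "deviation", "callus")),
      stringsAsFactors = FALSE)
  })

  results$table3 <- stage("dissected correlations", .table3Matrix(rec))

  results$table4 <- stage("longitudinal correlations", {
    out <- list()
    for (v in c("tibio", "keeldens", "xlm")) {
      m <- longitudinalMatrix(rec, v, timepoints = TIMEPOINTS)
      m <- cbind(variable = v, m)
      out[[v]] <- m
    }
    out
  })

  results$tukey <- stage("group comparisons", {
    rows <- lapply(c("deviation_size", "fracture_count", "callus_size"),
                   function(v) {
      tk <- suppressWarnings(groupMeansTukey(rec$xlm_dissected, rec[[v]]))
      cbind(score_variable = v, tk)
    })
    do.call(rbind, rows)
  })

  results$damageModels <- stage("damage models", {
    rows <- list()
    for (spec in damageSpecs) {
      for (tp in timepoints) {
        fit <- suppressWarnings(
          damageModel(rec, spec$response, spec$family, timepoint = tp))
        cf <- tidyCoef(fit)
        rows[[length(rows) + 1]] <-
          cbind(response = spec$response, family = spec$family,
                timepoint = tp, cf, n = fit@n)
      }
    }
    do.call(rbind, rows)
  })

  results$pelvicModels <- stage("pelvic models", {
    rows <- list()
    for (resp in pelvicResponses) {
      fits <- suppressWarnings(pelvicModel(rec, resp, "all"))
      for (pv in names(fits)) {
        cf <- tidyCoef(fits[[pv]])
        rows[[length(rows) + 1]] <-
          cbind(response = resp, pelvic = pv, cf, n = fits[[pv]]@n)
      }
    }
    do.call(rbind, rows)
  })

  stage("write outputs", {
    emit(results$frequencies, "table2_frequencies.csv")
    emit(results$cofrequencies, "cofrequencies.csv")
    emit(results$table3, "table3_correlations.csv")
    for (v in names(results$table4)) {
      emit(results$table4[[v]], sprintf("table4_%s.csv", v))
    }
    emit(results$tukey, "fig5_tukey.csv")
    emit(results$damageModels, "damage_models.csv")
    emit(results$pelvicModels, "pelvic_models.csv")
    emit(results$exclusions, "exclusions.csv")
  })

  manifest <- list(
    seed = if (is.null(config$seed)) NA else config$seed,
    n_input = nrow(records),
    n_retained = nrow(rec),
    n_excluded = nrow(results$exclusions),
    package_version = as.character(utils::packageVersion("keelmetry")),
    outputs = basename(written))
  manifestPath <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
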