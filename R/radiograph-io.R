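# Radiograph and annotation IO.
#
# DICOM support is a deliberately small codec: Part-10 files, little-endian
# explicit or implicit VR, uncompressed 8/16-bit monochrome pixel data,
# PixelSpacing and PhotometricInterpretation. That covers the files the
# phantom generator writes and plain monochrome exports from flat-panel
# detectors; anything else (compressed syntaxes, color, big-endian) is
# rejected with a clear error.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
IMPLICIT_VR_LE <- "1.2.840.10008.1.2"

.u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}

.u32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

.rawU16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

.rawU32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length.
.longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dicomElement <- function(group, element, vr, value) {
  if (vr %in% c("UI", "CS", "LO", "SH", "DS", "IS", "DA", "PN")) {
    v <- charToRaw(value)
    if (length(v) %% 2 == 1) {
      v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
    }
  } else if (vr == "US") {
    v <- .rawU16(value)
  } else if (vr == "OW") {
    v <- value
  } else {
    stop("unsupported VR in writer: ", vr)
  }
  header <- c(.rawU16(group), .rawU16(element), charToRaw(vr))
  if (vr %in% .longVRs) {
    header <- c(header, as.raw(c(0, 0)), .rawU32(length(v)))
  } else {
    header <- c(header, .rawU16(length(v)))
  }
  c(header, v)
}

#' Write a minimal monochrome DICOM file
#'
#' Writes an uncompressed little-endian explicit-VR Part-10 DICOM with
#' 16-bit monochrome pixel data. Intended for the phantom generator and for
#' round-trip tests; pixel values are rounded to integers and clamped to
#' [0, 65535].
#'
#' @param pixels numeric matrix of intensities.
#' @param path output file path.
#' @param mmPerPx pixel spacing in mm, or NA to omit the tag.
#' @param photometric \code{"MONOCHROME2"} (default; larger = brighter) or
#'   \code{"MONOCHROME1"} (inverted polarity, as some detectors encode).
#' @param birdId stored in PatientID.
#' @return \code{path}, invisibly.
#' @export
writeDicom <- function(pixels, path, mmPerPx = NA,
                       photometric = c("MONOCHROME2", "MONOCHROME1"),
                       birdId = "unknown") {
  photometric <- match.arg(photometric)
  vals <- round(pixels)
  if (any(vals < 0) || any(vals > 65535)) {
    stop("pixel values must fit in uint16 for DICOM export")
  }
  # row-major pixel order (row by row), 2 bytes little-endian each
  flat <- as.integer(t(vals))
  pixraw <- as.raw(rbind(flat %% 256L, flat %/% 256L))

  meta <- c(
    .dicomElement(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dicomElement(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9.9999.1"),
    .dicomElement(0x0002, 0x0010, "UI", EXPLICIT_VR_LE)
  )
  # group length element is UL (4-byte value), built by hand
  gl <- c(.rawU16(0x0002), .rawU16(0x0000), charToRaw("UL"), .rawU16(4),
          .rawU32(length(meta)))
  metaGroup <- c(gl, meta)

  dataset <- c(
    .dicomElement(0x0010, 0x0020, "LO", birdId),
    .dicomElement(0x0028, 0x0002, "US", 1),
    .dicomElement(0x0028, 0x0004, "CS", photometric),
    .dicomElement(0x0028, 0x0010, "US", nrow(vals)),
    .dicomElement(0x0028, 0x0011, "US", ncol(vals))
  )
  if (!is.na(mmPerPx)) {
    spacing <- sprintf("%.10g\\%.10g", mmPerPx, mmPerPx)
    dataset <- c(dataset, .dicomElement(0x0028, 0x0030, "DS", spacing))
  }
  dataset <- c(dataset,
    .dicomElement(0x0028, 0x0100, "US", 16),
    .dicomElement(0x0028, 0x0101, "US", 16),
    .dicomElement(0x0028, 0x0102, "US", 15),
    .dicomElement(0x0028, 0x0103, "US", 0),
    .dicomElement(0x7FE0, 0x0010, "OW", pixraw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(metaGroup, dataset), con)
  invisible(path)
}

# Parse a DICOM file into the fields the package needs.
.readDicomRaw <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("not a Part-10 DICOM file (missing DICM marker): ", path)
  }
  off <- 132L
  n <- length(raw)
  transfer <- EXPLICIT_VR_LE
  fields <- list()
  explicit <- TRUE
  inMeta <- TRUE
  while (off + 8 <= n) {
    group <- .u16(raw, off)
    element <- .u16(raw, off + 2)
    if (inMeta && group != 0x0002) {
      inMeta <- FALSE
      explicit <- (transfer == EXPLICIT_VR_LE)
      if (!transfer %in% c(EXPLICIT_VR_LE, IMPLICIT_VR_LE)) {
        stop("unsupported DICOM transfer syntax: ", transfer)
      }
    }
    if (inMeta || explicit) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% .longVRs) {
        len <- .u32(raw, off + 8)
        valOff <- off + 12
      } else {
        len <- .u16(raw, off + 6)
        valOff <- off + 8
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, off + 4)
      valOff <- off + 8
    }
    if (valOff + len > n) stop("truncated DICOM element at offset ", off)
    value <- raw[(valOff + 1):(valOff + len)]
    key <- sprintf("%04X,%04X", group, element)
    if (key == "0002,0010") {
      transfer <- trimws(rawToChar(value[value != as.raw(0)]))
    }
    fields[[key]] <- value
    off <- valOff + len
    if (key == "7FE0,0010") break
  }
  fields
}

.dicomString <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) return(NA_character_)
  trimws(rawToChar(v[v != as.raw(0)]))
}

.dicomU16 <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) return(NA_integer_)
  .u16(v, 0)
}

#' Load a radiograph
#'
#' Reads a DICOM, PNG or TIFF image into a \linkS4class{Radiograph} in the
#' canonical photometric orientation (larger value = denser tissue; sources
#' encoding the opposite polarity, e.g. DICOM MONOCHROME1, are inverted on
#' load as \code{max - pixels}). Pixel spacing comes from DICOM metadata when
#' present, else from \code{fallbackMmPerPx}, else the record is flagged
#' px-units-only (\code{mmPerPx = NA}).
#'
#' @param path file path; format chosen by extension
#'   (\code{.dcm}/\code{.dicom}, \code{.png}, \code{.tif}/\code{.tiff}).
#' @param fallbackMmPerPx pixel spacing to use when the file carries none.
#' @param birdId,timepoint metadata attached to the returned object
#'   (PatientID from DICOM is used when \code{birdId} is NA).
#' @return a \linkS4class{Radiograph}.
#' @export
loadRadiograph <- function(path, fallbackMmPerPx = NA, birdId = NA,
                           timepoint = NA) {
  if (!file.exists(path)) stop("cannot read radiograph file: ", path)
  ext <- tolower(tools::file_ext(path))
  spacing <- NA_real_
  if (ext %in% c("dcm", "dicom")) {
    fields <- .readDicomRaw(path)
    rows <- .dicomU16(fields, "0028,0010")
    cols <- .dicomU16(fields, "0028,0011")
    bits <- .dicomU16(fields, "0028,0100")
    if (is.na(rows) || is.na(cols)) stop("DICOM missing Rows/Columns: ", path)
    if (!is.na(bits) && !bits %in% c(8L, 16L)) {
      stop("unsupported BitsAllocated: ", bits)
    }
    pdat <- fields[["7FE0,0010"]]
    if (is.null(pdat)) stop("DICOM missing PixelData: ", path)
    if (is.na(bits)) bits <- 16L
    if (bits == 16L) {
      npx <- length(pdat) %/% 2L
      vals <- readBin(pdat, "integer", n = npx, size = 2, signed = FALSE,
                      endian = "little")
    } else {
      vals <- as.integer(pdat)
    }
    if (length(vals) < rows * cols) stop("DICOM pixel data truncated: ", path)
    mat <- matrix(as.numeric(vals[seq_len(rows * cols)]),
                  nrow = rows, ncol = cols, byrow = TRUE)
    phot <- .dicomString(fields, "0028,0004")
    if (identical(phot, "MONOCHROME1")) mat <- max(mat) - mat
    sp <- .dicomString(fields, "0028,0030")
    if (!is.na(sp)) {
      spacing <- suppressWarnings(as.numeric(strsplit(sp, "\\\\")[[1]][1]))
    }
    if (is.na(birdId)) birdId <- .dicomString(fields, "0010,0020")
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8
    if (length(dim(img)) == 3) img <- img[, , 1]
    mat <- img * (2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    img <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE))
    if (length(dim(img)) == 3) img <- img[, , 1]
    mat <- img * 1.0
  } else {
    stop("unsupported radiograph format: .", ext)
  }
  if (is.na(spacing) && !is.na(fallbackMmPerPx)) {
    spacing <- as.numeric(fallbackMmPerPx)
  }
  Radiograph(mat, mmPerPx = spacing, birdId = as.character(birdId),
             timepoint = as.character(timepoint),
             photometricNormalized = TRUE)
}

#' Write a radiograph as 16-bit TIFF
#'
#' @param image a \linkS4class{Radiograph} (values must fit in uint16).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTiff16 <- function(image, path) {
  vals <- round(pixels(image))
  if (any(vals < 0) || any(vals > 65535)) stop("values must fit in uint16")
  tiff::writeTIFF(vals / 65535, path, bits.per.sample = 16)
  invisible(path)
}

.annToList <- function(ann) {
  ptlist <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  out <- list(
    image_id = ann@imageId,
    tibiotarsal_line = ptlist(ann@tibiotarsalLine),
    keel_polyline = ptlist(ann@keelPolyline),
    middepth_line = ptlist(ann@middepthLine),
    cranialdepth_line = ptlist(ann@cranialdepthLine),
    keeldensity_anchor = list(point = unname(ann@densityAnchor$point),
                              direction = unname(ann@densityAnchor$direction))
  )
  if (length(ann@backgroundRegion) == 4) {
    out$background_region <- unname(ann@backgroundRegion)
  }
  out
}

.annFromList <- function(obj) {
  need <- c("image_id", "tibiotarsal_line", "keel_polyline", "middepth_line",
            "cranialdepth_line", "keeldensity_anchor")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop(sprintf("annotation '%s': missing field(s) %s",
                 if (is.null(obj$image_id)) "?" else obj$image_id,
                 paste(miss, collapse = ", ")))
  }
  toMat <- function(x, what) {
    m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
    if (ncol(m) != 2) {
      stop(sprintf("annotation '%s': %s points must be [x, y] pairs",
                   obj$image_id, what))
    }
    m
  }
  kp <- toMat(obj$keel_polyline, "keel_polyline")
  if (nrow(kp) < 2) {
    stop(sprintf("annotation '%s': keel_polyline needs at least 2 points",
                 obj$image_id))
  }
  KeelAnnotation(
    imageId = obj$image_id,
    tibiotarsalLine = toMat(obj$tibiotarsal_line, "tibiotarsal_line"),
    keelPolyline = kp,
    middepthLine = toMat(obj$middepth_line, "middepth_line"),
    cranialdepthLine = toMat(obj$cranialdepth_line, "cranialdepth_line"),
    densityAnchor = list(
      point = as.numeric(obj$keeldensity_anchor$point),
      direction = as.numeric(obj$keeldensity_anchor$direction)),
    backgroundRegion = if (is.null(obj$background_region)) numeric(0)
                       else as.numeric(obj$background_region))
}

#' Load keypoint annotations from a sidecar JSON file
#'
#' The file is a JSON array of objects with fields \code{image_id},
#' \code{tibiotarsal_line}, \code{keel_polyline}, \code{middepth_line},
#' \code{cranialdepth_line}, \code{keeldensity_anchor} (\code{point} +
#' \code{direction}) and optional \code{background_region}. Points are
#' \code{[x, y]} in 0-based pixel-center coordinates. Validation errors name
#' the offending image_id and field.
#'
#' @param path JSON file path.
#' @param imageSize optional \code{c(width, height)}; when given, every point
#'   is checked to lie within bounds.
#' @return named list of \linkS4class{KeelAnnotation} (names = image_id).
#' @export
loadAnnotations <- function(path, imageSize = NULL) {
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(objs)) stop("annotation file must contain a JSON array")
  anns <- lapply(objs, .annFromList)
  names(anns) <- vapply(anns, imageId, character(1))
  if (!is.null(imageSize)) {
    for (ann in anns) {
      pts <- rbind(ann@tibiotarsalLine, ann@keelPolyline, ann@middepthLine,
                   ann@cranialdepthLine, rbind(ann@densityAnchor$point))
      if (any(pts[, 1] < 0) || any(pts[, 1] > imageSize[1] - 1) ||
          any(pts[, 2] < 0) || any(pts[, 2] > imageSize[2] - 1)) {
        stop(sprintf("annotation '%s': point outside image bounds",
                     ann@imageId))
      }
    }
  }
  anns
}

#' Write keypoint annotations to JSON
#'
#' @param annotations list of \linkS4class{KeelAnnotation}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  jsonlite::write_json(lapply(unname(annotations), .annToList), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
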