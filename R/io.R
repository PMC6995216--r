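## File formats: annotation JSON/CSV, rating-table CSV, pattern reports,
## and DICOM pixel-spacing extraction for calibration.

#' Read a landmark annotation file
#'
#' JSON (primary) or CSV. The JSON schema is the one written by
#' [write_annotations()]: fields `view`, `injured_side`, `mm_per_px`,
#' optional `case_id`, optional `y_axis` (`"up"`, the internal
#' cephalad-positive convention, or `"down"` for screen coordinates, in
#' which case `image_height_px` is required and the vertical axis is
#' flipped on input), and `landmarks`, an array of
#' `{landmark, side, x_px, y_px}`. The CSV schema is one landmark per row
#' with columns `case_id`, `view`, `injured_side`, `mm_per_px`,
#' `landmark`, `side`, `x_px`, `y_px`. The landmark set is validated
#' against the view's catalog.
#'
#' @param path file path (`.json` or `.csv`).
#' @return A `view_annotation`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_pelvirad("pelvirad_error_io", "file not found: %s", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_pelvirad("pelvirad_error_schema",
                                  "cannot parse JSON in %s: %s", path,
                                  conditionMessage(e))
                  })
    return(annotation_from_list(x, source = path))
  }
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("view", "injured_side", "mm_per_px", "landmark", "side",
              "x_px", "y_px")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop_pelvirad("pelvirad_error_schema",
                    "%s is missing column(s): %s", path,
                    paste(miss, collapse = ", "))
    }
    if (length(unique(df$view)) != 1L ||
        length(unique(df$injured_side)) != 1L ||
        length(unique(df$mm_per_px)) != 1L) {
      stop_pelvirad("pelvirad_error_schema",
                    "%s mixes views, injured sides, or calibrations", path)
    }
    lm <- data.frame(landmark = df$landmark, side = df$side,
                     x = df$x_px, y = df$y_px, stringsAsFactors = FALSE)
    case_id <- if ("case_id" %in% names(df)) unique(df$case_id)[1L] else NULL
    return(view_annotation(df$view[1L], lm, df$mm_per_px[1L],
                           df$injured_side[1L], case_id = case_id))
  }
  stop_pelvirad("pelvirad_error_io",
                "unsupported annotation format '.%s' (use .json or .csv)",
                ext)
}

#' Write a landmark annotation file
#'
#' @param annotation a `view_annotation`.
#' @param path output path; `.json` or `.csv` selects the format.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path) {
  stopifnot(inherits(annotation, "view_annotation"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    json <- jsonlite::toJSON(annotation_to_list(annotation),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             null = "null")
    writeLines(json, path)
  } else if (ext == "csv") {
    lm <- annotation$landmarks
    df <- data.frame(
      case_id = if (is.null(annotation$case_id)) "" else annotation$case_id,
      view = annotation$view,
      injured_side = annotation$injured_side,
      mm_per_px = annotation$mm_per_px,
      landmark = lm$landmark, side = lm$side, x_px = lm$x, y_px = lm$y,
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop_pelvirad("pelvirad_error_io",
                  "unsupported annotation format '.%s' (use .json or .csv)",
                  ext)
  }
  invisible(path)
}

#' Read a long-format rating table from CSV
#'
#' Columns `observer`, `case`, `component`, `category`.
#'
#' @param path CSV path.
#' @return A `rating_table`.
#' @export
read_rating_table <- function(path) {
  if (!file.exists(path)) {
    stop_pelvirad("pelvirad_error_io", "file not found: %s", path)
  }
  rating_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a rating table to CSV
#'
#' @param table a `rating_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rating_table <- function(table, path) {
  if (!inherits(table, "rating_table")) table <- rating_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

## ---- DICOM pixel spacing -------------------------------------------------
## Minimal single-purpose part-10 tag walker: no installed R package reads
## DICOM, and only the PixelSpacing (0028,0030) metadata is needed for
## calibration. Supports explicit and implicit VR little endian.

read_uint <- function(raw, pos, n) {
  sum(as.integer(raw[pos:(pos + n - 1L)]) * 256^(seq_len(n) - 1L))
}

PR_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dicom_walk <- function(raw, pos, end, explicit, want_group, want_elem) {
  while (pos + 7L <= end) {
    group <- read_uint(raw, pos, 2L)
    elem <- read_uint(raw, pos + 2L, 2L)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% PR_LONG_VRS) {
        len <- read_uint(raw, pos + 4L, 4L)
        pos <- pos + 8L
      } else {
        len <- read_uint(raw, pos + 2L, 2L)
        pos <- pos + 4L
      }
    } else {
      len <- read_uint(raw, pos, 4L)
      pos <- pos + 4L
    }
    if (len == 4294967295) { # undefined length (sequence): not supported
      stop_pelvirad("pelvirad_error_dicom",
                    "unsupported undefined-length element (%04x,%04x)",
                    group, elem)
    }
    if (group == want_group && elem == want_elem) {
      if (len == 0L) return("")
      val <- raw[pos:(pos + len - 1L)]
      return(rawToChar(val[val != as.raw(0L)])) # strip NUL padding
    }
    pos <- pos + len
  }
  NULL
}

#' Read pixel spacing (mm/pixel) from a DICOM file
#'
#' Extracts the PixelSpacing attribute (tag 0028,0030) from a DICOM
#' part-10 file to calibrate pixel measurements. Only metadata is read;
#' explicit and implicit VR little endian transfer syntaxes are supported.
#' Anisotropic spacing (row spacing different from column spacing) is
#' rejected with advice to supply an explicit calibration, since the
#' measurement model assumes isotropic pixels.
#'
#' @param path DICOM file path.
#' @return A single numeric, mm per pixel.
#' @export
read_pixel_spacing <- function(path) {
  if (!file.exists(path)) {
    stop_pelvirad("pelvirad_error_io", "file not found: %s", path)
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L ||
      !identical(rawToChar(raw[129:132]), "DICM")) {
    stop_pelvirad("pelvirad_error_format",
                  "%s is not a DICOM part-10 file", path)
  }
  ## file meta group (0002) is always explicit VR little endian
  if (read_uint(raw, 133L, 2L) != 2L) {
    stop_pelvirad("pelvirad_error_dicom",
                  "%s has no file meta information group", path)
  }
  meta_vr <- rawToChar(raw[137:138])
  if (!identical(meta_vr, "UL")) {
    stop_pelvirad("pelvirad_error_dicom",
                  "%s: malformed file meta group length", path)
  }
  meta_len <- read_uint(raw, 141L, 4L)
  meta_end <- 144L + meta_len
  ts <- dicom_walk(raw, 145L, meta_end, explicit = TRUE, 2L, 16L) # (0002,0010)
  ts <- trimws(ts %||% "")
  explicit <- TRUE
  if (identical(ts, "1.2.840.10008.1.2")) {
    explicit <- FALSE
  } else if (!identical(ts, "1.2.840.10008.1.2.1") && nzchar(ts)) {
    stop_pelvirad("pelvirad_error_dicom",
                  "unsupported transfer syntax %s (little endian only)", ts)
  }
  val <- dicom_walk(raw, meta_end + 1L, length(raw), explicit,
                    40L, 48L) # (0028,0030)
  if (is.null(val)) {
    stop_pelvirad("pelvirad_error_dicom",
                  "%s has no PixelSpacing (0028,0030) attribute", path)
  }
  parts <- as.numeric(strsplit(trimws(val), "\\\\")[[1L]])
  if (length(parts) != 2L || anyNA(parts) || any(parts <= 0)) {
    stop_pelvirad("pelvirad_error_dicom",
                  "%s: malformed PixelSpacing value '%s'", path, val)
  }
  if (abs(parts[1L] - parts[2L]) > 1e-9) {
    stop_pelvirad("pelvirad_error_anisotropic",
                  "anisotropic pixel spacing (%g, %g) mm in %s; supply an explicit isotropic calibration instead",
                  parts[1L], parts[2L], path)
  }
  parts[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pattern report
#'
#' JSON report (pattern, thresholds, per-view text lines, package version)
#' mirroring the per-view phrasing of the clinical read-out.
#'
#' @param pattern a `displacement_pattern`.
#' @param path output JSON path.
#' @param case_id optional case identifier recorded in the report.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(pattern, path, case_id = NULL) {
  stopifnot(inherits(pattern, "displacement_pattern"))
  thr <- attr(pattern, "thresholds")
  x <- list(
    schema = "pelvirad_report/1",
    pelvirad_version = as.character(utils::packageVersion("pelvirad")),
    case_id = case_id,
    thresholds = if (is.null(thr)) NULL else unclass(thr),
    pattern = pattern_to_list(pattern),
    lines = as.list(unname(pattern_report_lines(pattern)))
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}
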