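#' Generate a complete synthetic case
#'
#' Composes the simulator end to end: the default symmetric template, a
#' known rigid displacement of one hemipelvis, orthographic projection to
#' the three standardized views, and optional per-landmark observer
#' jitter. The ground-truth pattern is obtained by thresholding the
#' displacement parameters with the classifier's own rule, so recovery can
#' be scored exactly.
#'
#' @param displacement a `rigid_displacement`.
#' @param sigma_mm observer jitter SD in mm (0 = noise-free).
#' @param seed optional integer seed controlling the jitter (one stream
#'   across the three views).
#' @param mm_per_px pixel calibration for the synthetic films.
#' @param thresholds `pr_thresholds` used for the ground-truth labels.
#' @param template the landmark template (default [default_template()]).
#' @param case_id optional identifier.
#' @return An object of class `synthetic_case`: list with elements
#'   `template`, `displacement`, `views` (named list of three
#'   `view_annotation`s), `truth` (a `displacement_pattern`), `sigma_mm`,
#'   `seed`, `case_id`.
#' @examples
#' cs <- make_case(rigid_displacement(ty = 10), sigma_mm = 0.5, seed = 1)
#' cs$truth
#' @export
make_case <- function(displacement, sigma_mm = 0, seed = NULL,
                      mm_per_px = 1, thresholds = pelvirad::thresholds(),
                      template = default_template(), case_id = NULL) {
  stopifnot(inherits(displacement, "rigid_displacement"))
  displaced <- apply_displacement(template, displacement)
  views <- lapply(stats::setNames(PR_VIEWS, PR_VIEWS), function(v) {
    project(displaced, v, mm_per_px = mm_per_px,
            injured_side = displacement$injured_side, case_id = case_id)
  })
  if (sigma_mm > 0) {
    views <- with_seed(seed, lapply(views, add_observer_jitter,
                                    sigma_mm = sigma_mm))
  }
  structure(
    list(template = template, displacement = displacement, views = views,
         truth = truth_pattern(displacement, thresholds),
         thresholds = thresholds, sigma_mm = sigma_mm, seed = seed,
         mm_per_px = mm_per_px, case_id = case_id),
    class = "synthetic_case"
  )
}

annotation_to_list <- function(ann) {
  list(
    view = ann$view,
    injured_side = ann$injured_side,
    mm_per_px = ann$mm_per_px,
    case_id = ann$case_id,
    y_axis = "up",
    landmarks = lapply(seq_len(nrow(ann$landmarks)), function(i) {
      r <- ann$landmarks[i, ]
      list(landmark = r$landmark, side = r$side, x_px = r$x, y_px = r$y)
    })
  )
}

annotation_from_list <- function(x, source = "annotation") {
  need <- c("view", "injured_side", "mm_per_px", "landmarks")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_pelvirad("pelvirad_error_schema",
                  "%s is missing field(s): %s", source,
                  paste(miss, collapse = ", "))
  }
  lm <- do.call(rbind, lapply(x$landmarks, function(l) {
    lmiss <- setdiff(c("landmark", "side", "x_px", "y_px"), names(l))
    if (length(lmiss)) {
      stop_pelvirad("pelvirad_error_schema",
                    "%s landmark entry missing field(s): %s", source,
                    paste(lmiss, collapse = ", "))
    }
    data.frame(landmark = l$landmark, side = l$side,
               x = as.numeric(l$x_px), y = as.numeric(l$y_px),
               stringsAsFactors = FALSE)
  }))
  y_axis <- if (is.null(x$y_axis)) "up" else x$y_axis
  if (identical(y_axis, "down")) {
    if (is.null(x$image_height_px)) {
      stop_pelvirad("pelvirad_error_schema",
                    "%s uses y_axis 'down' but has no image_height_px", source)
    }
    lm$y <- as.numeric(x$image_height_px) - lm$y
  } else if (!identical(y_axis, "up")) {
    stop_pelvirad("pelvirad_error_schema",
                  "%s has unknown y_axis '%s' (use 'up' or 'down')",
                  source, y_axis)
  }
  view_annotation(x$view, lm, as.numeric(x$mm_per_px), x$injured_side,
                  case_id = x$case_id)
}

#' Serialize a synthetic case to JSON
#'
#' The schema records the case id, seed, jitter level, displacement
#' parameters, the per-view landmark annotations, and the ground-truth
#' labels. Serialization is deterministic: the same case always produces
#' byte-identical output.
#'
#' @param case a `synthetic_case`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "synthetic_case"))
  d <- case$displacement
  x <- list(
    schema = "pelvirad_case/1",
    case_id = case$case_id,
    seed = case$seed,
    sigma_mm = case$sigma_mm,
    mm_per_px = case$mm_per_px,
    template_version = attr(case$template, "version"),
    displacement = list(
      translation = as.list(d$translation),
      rotation = as.list(d$rotation),
      center = d$center,
      injured_side = d$injured_side
    ),
    thresholds = unclass(case$thresholds),
    views = lapply(case$views, annotation_to_list),
    truth = pattern_to_list(case$truth)
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized synthetic case
#'
#' @param path path written by [write_case()].
#' @return A `synthetic_case`.
#' @export
read_case <- function(path) {
  if (!file.exists(path)) {
    stop_pelvirad("pelvirad_error_io", "file not found: %s", path)
  }
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$schema, "pelvirad_case/1")) {
    stop_pelvirad("pelvirad_error_schema",
                  "not a pelvirad case file: %s", path)
  }
  d <- x$displacement
  disp <- rigid_displacement(
    tx = d$translation$tx, ty = d$translation$ty, tz = d$translation$tz,
    sagittal = d$rotation$sagittal, axial = d$rotation$axial,
    coronal = d$rotation$coronal,
    injured_side = d$injured_side,
    center = if (is.null(d$center)) NULL else unlist(d$center)
  )
  thr <- thresholds(x$thresholds$translation_mm, x$thresholds$rotation_deg)
  views <- lapply(x$views, annotation_from_list, source = path)
  structure(
    list(template = default_template(x$template_version),
         displacement = disp, views = views,
         truth = pattern_from_list(x$truth),
         thresholds = thr,
         sigma_mm = x$sigma_mm,
         seed = x$seed, mm_per_px = x$mm_per_px, case_id = x$case_id),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  d <- x$displacement
  cat(sprintf("<synthetic_case>%s injured side %s, jitter %.3g mm\n",
              if (is.null(x$case_id)) "" else paste0(" ", x$case_id),
              d$injured_side, x$sigma_mm))
  cat(sprintf("  translation (mm): tx=%.3g ty=%.3g tz=%.3g\n",
              d$translation[["tx"]], d$translation[["ty"]],
              d$translation[["tz"]]))
  cat(sprintf("  rotation (deg): sagittal=%.3g axial=%.3g coronal=%.3g\n",
              d$rotation[["sagittal"]], d$rotation[["axial"]],
              d$rotation[["coronal"]]))
  cat("  truth:", format_pattern(x$truth), "\n")
  invisible(x)
}
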