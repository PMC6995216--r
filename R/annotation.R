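#' Construct a per-view landmark annotation
#'
#' One annotated standardized radiograph: 2D landmark pixel coordinates,
#' pixel calibration, and the injured-side flag. Internally the pixel frame
#' has its origin at the projected sacral endplate (world origin), the
#' horizontal axis increasing toward patient-left, and the vertical axis
#' increasing cephalad (inlet: anterior). File readers convert screen
#' coordinates (y down) on input; see [read_annotations()].
#'
#' @param view view name.
#' @param landmarks data.frame with columns `landmark`, `side`, `x`, `y`
#'   (pixels).
#' @param mm_per_px calibration, mm per pixel (> 0).
#' @param injured_side `"LEFT"` or `"RIGHT"`.
#' @param case_id optional case identifier.
#' @param validate check the landmark catalog against the view's
#'   requirements (default `TRUE`).
#' @return An object of class `view_annotation`.
#' @export
view_annotation <- function(view, landmarks, mm_per_px, injured_side,
                            case_id = NULL, validate = TRUE) {
  check_view(view)
  check_injured_side(injured_side)
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L ||
      !is.finite(mm_per_px) || mm_per_px <= 0) {
    stop_pelvirad("pelvirad_error_calibration",
                  "mm_per_px must be a single positive number")
  }
  need <- c("landmark", "side", "x", "y")
  if (!all(need %in% names(landmarks))) {
    stop_pelvirad("pelvirad_error_schema",
                  "annotation landmarks need columns %s",
                  paste(need, collapse = ", "))
  }
  landmarks <- as.data.frame(landmarks)[, need]
  if (validate) {
    req <- required_landmarks(view)
    bad <- setdiff(unique(landmarks$landmark), req)
    if (length(bad)) {
      stop_pelvirad("pelvirad_error_unknown_landmark",
                    "landmark(s) not in the %s catalog: %s",
                    view, paste(bad, collapse = ", "))
    }
    for (lm in setdiff(req, PR_MIDLINE_LANDMARK)) {
      for (sd in c("LEFT", "RIGHT")) {
        n <- sum(landmarks$landmark == lm & landmarks$side == sd)
        if (n != 1L) {
          stop_pelvirad("pelvirad_error_missing_landmark",
                        "%s view requires landmark %s on side %s exactly once (found %d)",
                        view, lm, sd, n)
        }
      }
    }
    if (PR_MIDLINE_LANDMARK %in% req) {
      n <- sum(landmarks$landmark == PR_MIDLINE_LANDMARK &
                 landmarks$side == "MIDLINE")
      if (n != 1L) {
        stop_pelvirad("pelvirad_error_missing_landmark",
                      "%s view requires landmark %s (MIDLINE) exactly once (found %d)",
                      view, PR_MIDLINE_LANDMARK, n)
      }
    }
    if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
      stop_pelvirad("pelvirad_error_schema",
                    "landmark coordinates must be finite")
    }
  }
  rownames(landmarks) <- NULL
  structure(
    list(view = view, landmarks = landmarks, mm_per_px = mm_per_px,
         injured_side = injured_side, case_id = case_id),
    class = "view_annotation"
  )
}

#' @export
print.view_annotation <- function(x, ...) {
  cat(sprintf("<view_annotation> %s view, injured side %s, %.4g mm/px\n",
              x$view, x$injured_side, x$mm_per_px))
  print(x$landmarks)
  invisible(x)
}

## landmark table in mm (same frame, scaled)
annotation_mm <- function(ann) {
  lm <- ann$landmarks
  lm$x <- lm$x * ann$mm_per_px
  lm$y <- lm$y * ann$mm_per_px
  lm
}

#' Orthographically project a template onto a standardized view
#'
#' Drops the view's out-of-plane axis, keeps only the landmarks in the
#' view's catalog, and converts mm to pixels with the given calibration.
#' The pixel origin is the projected world origin (sacral endplate), the
#' vertical pixel axis increases cephalad (inlet: anterior).
#'
#' @param template a `pelvis_template` (possibly displaced).
#' @param view view name.
#' @param mm_per_px calibration, mm per pixel (> 0).
#' @param injured_side which hemipelvis is flagged as injured.
#' @param case_id optional case identifier.
#' @return A `view_annotation`.
#' @examples
#' project(default_template(), "INLET", 1, injured_side = "LEFT")
#' @export
project <- function(template, view, mm_per_px = 1, injured_side = "LEFT",
                    case_id = NULL) {
  stopifnot(inherits(template, "pelvis_template"))
  check_view(view)
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L ||
      !is.finite(mm_per_px) || mm_per_px <= 0) {
    stop_pelvirad("pelvirad_error_calibration",
                  "mm_per_px must be a single positive number")
  }
  ax <- PR_VIEW_AXES[[view]]
  col_of <- c(X = "x", Y = "y", Z = "z")
  req <- required_landmarks(view)
  rows <- template[template$landmark %in% req, , drop = FALSE]
  lm <- data.frame(
    landmark = rows$landmark,
    side = rows$side,
    x = rows[[col_of[[ax$horizontal]]]] / mm_per_px,
    y = rows[[col_of[[ax$vertical]]]] / mm_per_px,
    stringsAsFactors = FALSE
  )
  view_annotation(view, lm, mm_per_px, injured_side, case_id = case_id)
}

## evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add simulated observer landmark-picking jitter
#'
#' Adds independent isotropic Gaussian offsets (SD `sigma_mm`, converted to
#' pixels via the annotation's calibration) to every landmark, modeling the
#' variability of a human observer clicking landmarks on a radiograph.
#'
#' @param annotation a `view_annotation`.
#' @param sigma_mm jitter standard deviation in mm (>= 0); 0 returns the
#'   annotation unchanged.
#' @param seed optional integer seed; a fixed seed makes the jitter
#'   reproducible without disturbing the caller's RNG state.
#' @return A jittered `view_annotation`.
#' @export
add_observer_jitter <- function(annotation, sigma_mm, seed = NULL) {
  stopifnot(inherits(annotation, "view_annotation"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L ||
      !is.finite(sigma_mm) || sigma_mm < 0) {
    stop_pelvirad("pelvirad_error_sigma",
                  "sigma_mm must be a single non-negative number")
  }
  if (sigma_mm == 0) return(annotation)
  n <- nrow(annotation$landmarks)
  sigma_px <- sigma_mm / annotation$mm_per_px
  eps <- with_seed(seed, matrix(stats::rnorm(2L * n, sd = sigma_px), n, 2L))
  annotation$landmarks$x <- annotation$landmarks$x + eps[, 1L]
  annotation$landmarks$y <- annotation$landmarks$y + eps[, 2L]
  annotation
}
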