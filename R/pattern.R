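#' Detection thresholds
#'
#' Offsets are classified PRESENT when their magnitude reaches the
#' threshold (ties inclusive). Defaults are 5 mm / 5 degrees: half the
#' 10 mm residual-deformity bound that the trauma literature links to poor
#' prognosis, taken as the detection floor.
#'
#' @param translation_mm translation threshold in mm (> 0).
#' @param rotation_deg rotation threshold in degrees (> 0).
#' @return An object of class `pr_thresholds`.
#' @export
thresholds <- function(translation_mm = 5, rotation_deg = 5) {
  if (!is.numeric(translation_mm) || length(translation_mm) != 1L ||
      !is.finite(translation_mm) || translation_mm <= 0 ||
      !is.numeric(rotation_deg) || length(rotation_deg) != 1L ||
      !is.finite(rotation_deg) || rotation_deg <= 0) {
    stop_pelvirad("pelvirad_error_thresholds",
                  "thresholds must be single positive numbers")
  }
  structure(list(translation_mm = translation_mm,
                 rotation_deg = rotation_deg),
            class = "pr_thresholds")
}

component_threshold <- function(component, thr) {
  if (component %in% PR_TRANSLATIONS) thr$translation_mm else thr$rotation_deg
}

#' Construct a six-component displacement pattern
#'
#' @param status named character vector (`"PRESENT"`/`"ABSENT"`) over the
#'   six components.
#' @param direction named character vector of anatomical direction labels
#'   (`NA` where absent).
#' @param injured_side `"LEFT"` or `"RIGHT"`.
#' @param offsets optional named numeric vector of the measured signed
#'   offsets (mm / degrees); kept internally for thresholding, not a
#'   validated clinical magnitude.
#' @param thresholds the `pr_thresholds` used.
#' @return An object of class `displacement_pattern` (a data.frame with
#'   one row per component).
#' @export
displacement_pattern <- function(status, direction, injured_side,
                                 offsets = NULL, thresholds = NULL) {
  check_injured_side(injured_side)
  stopifnot(all(PR_COMPONENTS %in% names(status)),
            all(PR_COMPONENTS %in% names(direction)))
  st <- unname(status[PR_COMPONENTS])
  dir <- unname(direction[PR_COMPONENTS])
  if (!all(st %in% c("PRESENT", "ABSENT"))) {
    stop_pelvirad("pelvirad_error_pattern",
                  "status must be PRESENT or ABSENT")
  }
  if (any(st == "PRESENT" & is.na(dir)) || any(st == "ABSENT" & !is.na(dir))) {
    stop_pelvirad("pelvirad_error_pattern",
                  "direction must be given exactly for PRESENT components")
  }
  df <- data.frame(component = PR_COMPONENTS, status = st, direction = dir,
                   stringsAsFactors = FALSE)
  structure(df, class = c("displacement_pattern", "data.frame"),
            injured_side = injured_side,
            offsets = offsets,
            thresholds = thresholds)
}

pattern_from_offsets <- function(offsets, injured_side, thr) {
  status <- direction <- stats::setNames(rep(NA_character_, 6L), PR_COMPONENTS)
  for (comp in PR_COMPONENTS) {
    v <- offsets[[comp]]
    if (abs(v) >= component_threshold(comp, thr)) {
      status[comp] <- "PRESENT"
      direction[comp] <- direction_label(comp, injured_side, v)
    } else {
      status[comp] <- "ABSENT"
    }
  }
  displacement_pattern(status, direction, injured_side,
                       offsets = offsets[PR_COMPONENTS], thresholds = thr)
}

#' Ground-truth pattern of a rigid displacement
#'
#' Thresholds the six ground-truth displacement parameters directly,
#' using the same rule and direction conventions as the classifier.
#'
#' @param d a `rigid_displacement`.
#' @param thresholds a `pr_thresholds`.
#' @return A `displacement_pattern`.
#' @export
truth_pattern <- function(d, thresholds = pelvirad::thresholds()) {
  stopifnot(inherits(d, "rigid_displacement"))
  offsets <- c(
    TRANS_X = unname(d$translation[["tx"]]),
    TRANS_Y = unname(d$translation[["ty"]]),
    TRANS_Z = unname(d$translation[["tz"]]),
    ROT_SAGITTAL = unname(d$rotation[["sagittal"]]),
    ROT_AXIAL = unname(d$rotation[["axial"]]),
    ROT_CORONAL = unname(d$rotation[["coronal"]])
  )
  pattern_from_offsets(offsets, d$injured_side, thresholds)
}

## components present in a view, rendered as the per-view phrase
view_phrase <- function(pattern, view) {
  comps <- PR_VIEW_COMPONENTS[[view]]
  rows <- pattern[pattern$component %in% comps & pattern$status == "PRESENT", ]
  if (!nrow(rows)) return("")
  labels <- vapply(seq_len(nrow(rows)), function(i) {
    lab <- rows$direction[i]
    if (rows$component[i] == "ROT_AXIAL") paste(lab, "rotation") else lab
  }, character(1))
  paste(labels, collapse = ", ")
}

pr_view_display <- c(AP = "AP", OUTLET = "outlet", INLET = "inlet")

#' Format a pattern as the compact per-view report string
#'
#' Renders the classification the way the clinical report phrases it, one
#' clause per view with findings, e.g.
#' `"extension (AP); cephalad (outlet); medial, anterior, internal rotation (inlet)"`.
#'
#' @param pattern a `displacement_pattern`.
#' @return A single string; `"no displacement"` if all six components are
#'   absent.
#' @export
format_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "displacement_pattern"))
  parts <- character(0)
  for (v in c("AP", "OUTLET", "INLET")) {
    ph <- view_phrase(pattern, v)
    if (nzchar(ph)) {
      parts <- c(parts, sprintf("%s (%s)", ph, pr_view_display[[v]]))
    }
  }
  if (!length(parts)) return("no displacement")
  paste(parts, collapse = "; ")
}

## one line per view, always emitted (for text reports)
pattern_report_lines <- function(pattern) {
  vapply(c("AP", "OUTLET", "INLET"), function(v) {
    ph <- view_phrase(pattern, v)
    sprintf("%s: %s", pr_view_display[[v]], if (nzchar(ph)) ph else "none")
  }, character(1))
}

#' @export
print.displacement_pattern <- function(x, ...) {
  cat(sprintf("<displacement_pattern> injured side %s\n",
              attr(x, "injured_side")))
  print(as.data.frame(x))
  cat(format_pattern(x), "\n")
  invisible(x)
}

## stable categorical rating per component: direction label or "absent"
pattern_categories <- function(pattern) {
  out <- ifelse(pattern$status == "PRESENT", pattern$direction, "absent")
  stats::setNames(out, pattern$component)
}

patterns_equal <- function(a, b) {
  identical(pattern_categories(a), pattern_categories(b))
}

pattern_to_list <- function(pattern) {
  list(
    injured_side = attr(pattern, "injured_side"),
    components = lapply(stats::setNames(PR_COMPONENTS, PR_COMPONENTS),
      function(comp) {
        i <- match(comp, pattern$component)
        list(status = pattern$status[i],
             direction = if (is.na(pattern$direction[i])) NULL
                         else pattern$direction[i])
      }),
    report = format_pattern(pattern)
  )
}

pattern_from_list <- function(x) {
  status <- vapply(PR_COMPONENTS, function(c) x$components[[c]]$status,
                   character(1))
  direction <- vapply(PR_COMPONENTS, function(c) {
    d <- x$components[[c]]$direction
    if (is.null(d)) NA_character_ else d
  }, character(1))
  displacement_pattern(status, direction, x$injured_side)
}
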