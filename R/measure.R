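## Measurement engine: mirror the intact hemipelvis across the midsagittal
## reference, measure per-view translational/rotational offsets of the
## injured side against its mirrored expectation, and classify into the
## six basic displacement patterns.

#' Midsagittal reference line of a view
#'
#' Returns the horizontal pixel position of the vertical mirror line. For
#' the inlet and outlet views this is the projected sacral endplate
#' landmark; the AP catalog carries no midline landmark, so the AP view
#' falls back to the vertical bisector of the two ischial tuberosities.
#'
#' @param annotation a `view_annotation`.
#' @return Horizontal position of the mirror line, in pixels.
#' @export
midline_reference <- function(annotation) {
  stopifnot(inherits(annotation, "view_annotation"))
  lm <- annotation$landmarks
  mid <- lm$landmark == PR_MIDLINE_LANDMARK & lm$side == "MIDLINE"
  if (any(mid)) return(lm$x[mid][1L])
  it <- lm$landmark == "ISCHIAL_TUBEROSITY"
  if (sum(it) == 2L) return(mean(lm$x[it]))
  stop_pelvirad("pelvirad_error_midline",
                "%s view has no midline landmark and no bilateral fallback",
                annotation$view)
}

#' Mirror the intact hemipelvis across the reference line
#'
#' Reflects the intact (contralateral) side's bilateral landmarks across
#' the vertical mirror line, yielding the expected undisplaced positions
#' of the injured side's landmarks.
#'
#' @param annotation a `view_annotation`.
#' @param line mirror-line horizontal position in pixels; default
#'   [midline_reference()].
#' @return data.frame with columns `landmark`, `x`, `y` (pixels).
#' @export
mirror_intact <- function(annotation, line = NULL) {
  stopifnot(inherits(annotation, "view_annotation"))
  if (is.null(line)) line <- midline_reference(annotation)
  intact <- opposite_side(annotation$injured_side)
  req <- setdiff(required_landmarks(annotation$view), PR_MIDLINE_LANDMARK)
  lm <- annotation$landmarks
  out <- lapply(req, function(l) {
    i <- which(lm$landmark == l & lm$side == intact)
    if (!length(i)) {
      stop_pelvirad("pelvirad_error_missing_landmark",
                    "intact-side landmark %s missing from %s view",
                    l, annotation$view)
    }
    data.frame(landmark = l, x = 2 * line - lm$x[i[1L]], y = lm$y[i[1L]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

signed_angle_deg <- function(u, v) {
  atan2(u[1L] * v[2L] - u[2L] * v[1L],
        u[1L] * v[1L] + u[2L] * v[2L]) * 180 / pi
}

segment_of <- function(df, from, to) {
  a <- df[match(from, df$landmark), c("x", "y")]
  b <- df[match(to, df$landmark), c("x", "y")]
  as.numeric(b) - as.numeric(a)
}

## template geometry (mm, world frame) for the injured side of one view
template_view_geometry <- function(view, injured_side,
                                   template = default_template()) {
  ax <- PR_VIEW_AXES[[view]]
  col_of <- c(X = 1L, Y = 2L, Z = 3L)
  pts3 <- template_points(template, injured_side, PR_BILATERAL_LANDMARKS)
  center3 <- colMeans(pts3)
  seg <- PR_VIEW_SEGMENT[[view]]
  seg3 <- pts3[seg[2L], ] - pts3[seg[1L], ]
  plane <- c(col_of[[ax$horizontal]], col_of[[ax$vertical]])
  viewset <- intersect(required_landmarks(view), PR_BILATERAL_LANDMARKS)
  list(
    pts3 = pts3, center3 = center3, seg3 = seg3, plane = plane,
    viewset = viewset,
    seg2 = seg3[plane],
    seg_len2 = sqrt(sum(seg3[plane]^2))
  )
}

## normalize an angle to (-180, 180]
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

## Solve the AP foreshortening equation for the sagittal angle.
## Observed vertical segment component v_y relates to the expected 3D
## segment d (after applying known axial/coronal rotations) by
##   v_y = d_y cos(s) - d_z sin(s);
## of the two solutions the one of smaller magnitude is taken (patterns
## are small rigid displacements).
solve_sagittal <- function(d3, vy) {
  a <- d3[2L]
  b <- -d3[3L]
  r <- sqrt(a^2 + b^2)
  if (r < 1e-9) {
    stop_pelvirad("pelvirad_error_degenerate",
                  "AP segment has no vertical/out-of-plane lever")
  }
  phi <- atan2(b, a)
  x <- min(1, max(-1, vy / r))
  cand <- wrap_angle(c(phi + acos(x), phi - acos(x)) * 180 / pi)
  cand[which.min(abs(cand))]
}

## mirrored-intact ("expected") and injured ("observed") bilateral landmark
## tables of a view, in mm
view_landmark_tables <- function(annotation, landmarks = NULL) {
  v <- annotation$view
  lm <- annotation_mm(annotation)
  line_mm <- midline_reference(annotation) * annotation$mm_per_px
  intact <- opposite_side(annotation$injured_side)
  if (is.null(landmarks)) {
    landmarks <- intersect(required_landmarks(v), PR_BILATERAL_LANDMARKS)
  }
  expected <- do.call(rbind, lapply(landmarks, function(l) {
    i <- which(lm$landmark == l & lm$side == intact)
    if (!length(i)) {
      stop_pelvirad("pelvirad_error_missing_landmark",
                    "intact-side landmark %s missing from %s view", l, v)
    }
    data.frame(landmark = l, x = 2 * line_mm - lm$x[i[1L]], y = lm$y[i[1L]])
  }))
  observed <- do.call(rbind, lapply(landmarks, function(l) {
    i <- which(lm$landmark == l & lm$side == annotation$injured_side)
    if (!length(i)) {
      stop_pelvirad("pelvirad_error_missing_landmark",
                    "injured-side landmark %s missing from %s view", l, v)
    }
    data.frame(landmark = l, x = lm$x[i[1L]], y = lm$y[i[1L]])
  }))
  list(expected = expected, observed = observed)
}

## Sagittal angle by least squares over several segments of the X/Y
## projection plane (AP film segment plus the outlet film's three landmark
## pairs). Single-segment inversion of the foreshortening equation is
## ill-conditioned where the segment's apparent vertical extent is
## stationary in the angle; pairs with opposite anteroposterior levers
## (e.g. iliac wing -> ASIS vs ASIS -> ischial tuberosity) keep the joint
## problem well conditioned throughout the working range.
estimate_sagittal <- function(ap, outlet, axial, coronal,
                              template = default_template()) {
  side <- ap$injured_side
  pts3 <- template_points(template, side, PR_BILATERAL_LANDMARKS)
  segs <- list(
    list(ann = ap, pair = c("ASIS", "ISCHIAL_TUBEROSITY")),
    list(ann = outlet, pair = c("SUPERIOR_ILIAC_WING", "ISCHIAL_TUBEROSITY")),
    list(ann = outlet, pair = c("SUPERIOR_ILIAC_WING", "ASIS")),
    list(ann = outlet, pair = c("ASIS", "ISCHIAL_TUBEROSITY"))
  )
  Rac <- rot_y(axial) %*% rot_z(coronal)
  terms <- lapply(segs, function(sg) {
    tabs <- view_landmark_tables(sg$ann, landmarks = sg$pair)
    u <- segment_of(tabs$expected, sg$pair[1L], sg$pair[2L])
    w <- segment_of(tabs$observed, sg$pair[1L], sg$pair[2L])
    dz_t <- pts3[sg$pair[2L], 3L] - pts3[sg$pair[1L], 3L]
    seg2_t <- pts3[sg$pair[2L], 1:2] - pts3[sg$pair[1L], 1:2]
    scale <- sqrt(sum(u^2)) / sqrt(sum(seg2_t^2))
    d3 <- as.numeric(Rac %*% c(u[1L], u[2L], scale * dz_t))
    c(a = d3[2L], b = -d3[3L], c = w[2L])
  })
  sse <- function(s) {
    rad <- s * pi / 180
    sum(vapply(terms, function(t) {
      (t[["a"]] * cos(rad) + t[["b"]] * sin(rad) - t[["c"]])^2
    }, numeric(1)))
  }
  stats::optimize(sse, interval = c(-60, 60), tol = 1e-10)$minimum
}

#' Measure one annotated view
#'
#' Mirrors the intact side, then measures the view's detectable
#' components: rotations as the signed angle between the injured-side
#' landmark segment and its mirrored-intact counterpart (inlet/outlet;
#' in-plane), or by inverting the projective foreshortening of the AP
#' segment (sagittal rotation is out of the AP plane); translations as
#' the centroid offset of the injured side's landmarks from their
#' mirrored expectation, with the rotation-induced part of the centroid
#' motion (predicted from the scaled template about the hemipelvic
#' centroid) subtracted.
#'
#' @param annotation a `view_annotation`.
#' @param context optional named list with rotation estimates (degrees)
#'   from the other views: `sagittal`, `axial`, `coronal`. Components not
#'   supplied are taken as 0. [measure_case()] threads these
#'   automatically; a standalone call measures with the view's own
#'   information only.
#' @param template landmark template used for the out-of-plane lever and
#'   the rotation-compensation geometry.
#' @return An object of class `view_measurement`: list with `view`,
#'   `offsets` (named numeric over the view's detectable components; mm
#'   for translations, degrees for rotations), `injured_side`, `scale`.
#' @export
measure_view <- function(annotation, context = list(),
                         template = default_template()) {
  stopifnot(inherits(annotation, "view_annotation"))
  v <- annotation$view
  geo <- template_view_geometry(v, annotation$injured_side, template)

  ## expected (mirrored intact) and observed (injured) bilateral landmarks
  tabs <- view_landmark_tables(annotation, landmarks = geo$viewset)
  expected <- tabs$expected
  observed <- tabs$observed

  seg_names <- PR_VIEW_SEGMENT[[v]]
  u <- segment_of(expected, seg_names[1L], seg_names[2L])
  w <- segment_of(observed, seg_names[1L], seg_names[2L])
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9) {
    stop_pelvirad("pelvirad_error_degenerate",
                  "degenerate (coincident) segment landmarks in %s view", v)
  }
  scale <- sqrt(sum(u^2)) / geo$seg_len2

  ctx <- function(nm) {
    x <- context[[nm]]
    if (is.null(x) || !is.finite(x)) 0 else as.numeric(x)
  }

  offsets <- numeric(0)
  if (v == "INLET") {
    axial <- -signed_angle_deg(u, w)
    rot <- c(sagittal = ctx("sagittal"), axial = axial,
             coronal = ctx("coronal"))
  } else if (v == "OUTLET") {
    coronal <- signed_angle_deg(u, w)
    rot <- c(sagittal = ctx("sagittal"), axial = ctx("axial"),
             coronal = coronal)
  } else { # AP
    d3 <- c(u[1L], u[2L], scale * geo$seg3[3L])
    d3 <- as.numeric(rot_y(ctx("axial")) %*% rot_z(ctx("coronal")) %*% d3)
    sagittal <- solve_sagittal(d3, w[2L])
    rot <- c(sagittal = sagittal, axial = ctx("axial"),
             coronal = ctx("coronal"))
  }

  if (v %in% c("INLET", "OUTLET")) {
    ## rotation-compensated centroid offset -> translation along the
    ## view's world axes
    obs_off <- colMeans(observed[, c("x", "y")]) - colMeans(expected[, c("x", "y")])
    R <- rotation_matrix(rot[["sagittal"]], rot[["axial"]], rot[["coronal"]])
    rel <- sweep(geo$pts3[geo$viewset, , drop = FALSE], 2, geo$center3)
    pred3 <- colMeans(rel %*% t(R) - rel) * scale
    pred <- pred3[geo$plane]
    t2 <- as.numeric(obs_off) - pred
    if (v == "INLET") {
      offsets <- c(TRANS_X = t2[1L], TRANS_Z = t2[2L],
                   ROT_AXIAL = rot[["axial"]])
    } else {
      offsets <- c(TRANS_Y = t2[2L], ROT_CORONAL = rot[["coronal"]])
    }
  } else {
    offsets <- c(ROT_SAGITTAL = rot[["sagittal"]])
  }

  offsets <- offsets[PR_VIEW_COMPONENTS[[v]]]
  if (!all(is.finite(offsets))) {
    stop_pelvirad("pelvirad_error_degenerate",
                  "non-finite measurement in %s view", v)
  }
  structure(
    list(view = v, offsets = offsets,
         injured_side = annotation$injured_side, scale = scale),
    class = "view_measurement"
  )
}

#' @export
print.view_measurement <- function(x, ...) {
  cat(sprintf("<view_measurement> %s view, injured side %s\n",
              x$view, x$injured_side))
  print(round(x$offsets, 4))
  invisible(x)
}

#' Classify per-view measurements into a displacement pattern
#'
#' A component is PRESENT when the magnitude of its measured offset
#' reaches the threshold (ties classified PRESENT); its anatomical
#' direction follows the sign conventions of [direction_conventions()].
#'
#' @param measurements list of three `view_measurement`s (one per view).
#' @param thresholds a `pr_thresholds`.
#' @return A `displacement_pattern`.
#' @export
classify <- function(measurements, thresholds = pelvirad::thresholds()) {
  if (!is.list(measurements) ||
      !all(vapply(measurements, inherits, logical(1), "view_measurement"))) {
    stop_pelvirad("pelvirad_error_measurements",
                  "classify() expects a list of view_measurement objects")
  }
  views <- vapply(measurements, `[[`, character(1), "view")
  missing <- setdiff(PR_VIEWS, views)
  if (length(missing)) {
    stop_pelvirad("pelvirad_error_missing_view",
                  "missing view measurement(s): %s",
                  paste(missing, collapse = ", "))
  }
  sides <- unique(vapply(measurements, `[[`, character(1), "injured_side"))
  if (length(sides) != 1L) {
    stop_pelvirad("pelvirad_error_inconsistent",
                  "conflicting injured-side flags: %s",
                  paste(sides, collapse = ", "))
  }
  offsets <- stats::setNames(rep(NA_real_, 6L), PR_COMPONENTS)
  for (m in measurements) offsets[names(m$offsets)] <- m$offsets
  if (anyNA(offsets)) {
    stop_pelvirad("pelvirad_error_missing_view",
                  "measurements do not cover all six components")
  }
  pattern_from_offsets(offsets, sides, thresholds)
}

#' Measure a full case (three views) and classify it
#'
#' The full pipeline: midsagittal reference, mirrored intact side, per-view
#' offsets, classification. Rotation estimates are threaded between views:
#' the in-plane inlet (axial) and outlet (coronal) angles are measured
#' first and passed into the AP sagittal solve, then all three rotation
#' estimates feed the rotation compensation of the translation
#' measurements.
#'
#' @param ap,inlet,outlet the three `view_annotation`s, or pass a
#'   `synthetic_case` as `ap` to measure its views.
#' @param thresholds a `pr_thresholds`.
#' @param template landmark template for measurement geometry.
#' @return A `displacement_pattern`.
#' @examples
#' cs <- make_case(rigid_displacement(ty = 10))
#' measure_case(cs)
#' @export
measure_case <- function(ap, inlet = NULL, outlet = NULL,
                         thresholds = pelvirad::thresholds(),
                         template = default_template()) {
  if (inherits(ap, "synthetic_case")) {
    views <- ap$views
    ap <- views$AP; inlet <- views$INLET; outlet <- views$OUTLET
  }
  for (x in list(ap, inlet, outlet)) {
    if (!inherits(x, "view_annotation")) {
      stop_pelvirad("pelvirad_error_missing_view",
                    "measure_case() needs AP, inlet, and outlet annotations")
    }
  }
  anns <- list(ap, inlet, outlet)
  got <- vapply(anns, `[[`, character(1), "view")
  if (!setequal(got, PR_VIEWS) || anyDuplicated(got)) {
    stop_pelvirad("pelvirad_error_missing_view",
                  "need one annotation per view (AP, INLET, OUTLET); got %s",
                  paste(got, collapse = ", "))
  }
  names(anns) <- got
  sides <- unique(vapply(anns, `[[`, character(1), "injured_side"))
  if (length(sides) != 1L) {
    stop_pelvirad("pelvirad_error_inconsistent",
                  "conflicting injured-side flags: %s",
                  paste(sides, collapse = ", "))
  }

  m_in <- measure_view(anns$INLET, template = template)
  m_out <- measure_view(anns$OUTLET, template = template)
  ctx <- list(axial = m_in$offsets[["ROT_AXIAL"]],
              coronal = m_out$offsets[["ROT_CORONAL"]])
  ## sagittal: multi-segment least squares across the AP/outlet plane,
  ## better conditioned than the AP film's single segment
  sagittal <- estimate_sagittal(anns$AP, anns$OUTLET,
                                axial = ctx$axial, coronal = ctx$coronal,
                                template = template)
  m_ap <- structure(
    list(view = "AP", offsets = c(ROT_SAGITTAL = sagittal),
         injured_side = sides, scale = NA_real_),
    class = "view_measurement"
  )
  ctx$sagittal <- sagittal
  m_in <- measure_view(anns$INLET, context = ctx, template = template)
  m_out <- measure_view(anns$OUTLET, context = ctx, template = template)

  classify(list(m_ap, m_in, m_out), thresholds)
}
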