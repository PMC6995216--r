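#' Specify a 6-DOF rigid displacement of one hemipelvis
#'
#' Encodes the ground-truth deformity applied by the simulator: a rotation
#' (intrinsic order sagittal, then axial, then coronal) about a rotation
#' center, followed by a translation, applied to the landmarks of the
#' injured hemipelvis only.
#'
#' Rotation sign conventions (right-handed about the world axes):
#' positive sagittal rotation (about X, mediolateral) is flexion — the
#' ASIS moves caudad; positive axial rotation (about Y) carries the
#' anterior structures of a LEFT hemipelvis laterally (external rotation;
#' internal for a RIGHT hemipelvis); positive coronal rotation (about Z)
#' is adduction of a LEFT hemipelvis. See [direction_conventions()].
#'
#' @param tx,ty,tz translation in mm along X (mediolateral, + toward
#'   patient-left), Y (craniocaudal, + cephalad), Z (anteroposterior,
#'   + anterior).
#' @param sagittal,axial,coronal rotation angles in degrees.
#' @param injured_side `"LEFT"` or `"RIGHT"`.
#' @param center optional 3-vector rotation center (mm); default is the
#'   centroid of the injured hemipelvis's four landmarks, resolved when
#'   the displacement is applied.
#' @return An object of class `rigid_displacement`.
#' @examples
#' rigid_displacement(ty = 10, injured_side = "LEFT")
#' @export
rigid_displacement <- function(tx = 0, ty = 0, tz = 0,
                               sagittal = 0, axial = 0, coronal = 0,
                               injured_side = "LEFT", center = NULL) {
  check_injured_side(injured_side)
  vals <- c(tx, ty, tz, sagittal, axial, coronal)
  if (!all(is.finite(vals))) {
    stop_pelvirad("pelvirad_error_displacement",
                  "displacement parameters must be finite")
  }
  if (!is.null(center) && (length(center) != 3L || !all(is.finite(center)))) {
    stop_pelvirad("pelvirad_error_displacement",
                  "rotation center must be a finite 3-vector")
  }
  structure(
    list(
      translation = c(tx = tx, ty = ty, tz = tz),
      rotation = c(sagittal = sagittal, axial = axial, coronal = coronal),
      center = center,
      injured_side = injured_side
    ),
    class = "rigid_displacement"
  )
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

## composed rotation, intrinsic order sagittal(X) -> axial(Y) -> coronal(Z)
rotation_matrix <- function(sagittal, axial, coronal) {
  rot_x(sagittal) %*% rot_y(axial) %*% rot_z(coronal)
}

#' Apply a rigid displacement to the injured hemipelvis
#'
#' Rotates the injured side's landmarks about the rotation center
#' (intrinsic order sagittal, axial, coronal) and then translates them;
#' contralateral and midline landmarks are untouched. The transform is
#' rigid: all pairwise distances within the displaced hemipelvis are
#' preserved.
#'
#' @param template a `pelvis_template`.
#' @param d a `rigid_displacement`.
#' @return A displaced `pelvis_template`.
#' @examples
#' tpl <- default_template()
#' d <- rigid_displacement(ty = 10, injured_side = "LEFT")
#' apply_displacement(tpl, d)
#' @export
apply_displacement <- function(template, d) {
  stopifnot(inherits(template, "pelvis_template"),
            inherits(d, "rigid_displacement"))
  check_injured_side(d$injured_side)
  ctr <- d$center
  if (is.null(ctr)) ctr <- hemipelvis_centroid(template, d$injured_side)
  R <- rotation_matrix(d$rotation[["sagittal"]], d$rotation[["axial"]],
                       d$rotation[["coronal"]])
  out <- template
  idx <- out$side == d$injured_side
  P <- as.matrix(out[idx, c("x", "y", "z")])
  P2 <- sweep(P, 2, ctr) %*% t(R)
  P2 <- sweep(P2, 2, ctr + unname(d$translation), "+")
  out[idx, c("x", "y", "z")] <- P2
  out
}
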