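#' @keywords internal
"_PACKAGE"

## Pelvis-specific frame: X mediolateral (positive toward patient-left),
## Y craniocaudal (positive cephalad), Z anteroposterior (positive anterior).
## Origin at the trailing (posterior) edge of the S1 superior endplate;
## the midsagittal plane is X = 0.

PR_AXES <- c("X", "Y", "Z")
PR_VIEWS <- c("AP", "INLET", "OUTLET")
PR_SIDES <- c("LEFT", "RIGHT", "MIDLINE")

PR_LANDMARKS <- c(
  "ASIS",
  "ISCHIAL_TUBEROSITY",
  "SUPERIOR_ILIAC_WING",
  "ANTERIOR_SI_JOINT_ILIAC",
  "SACRAL_ENDPLATE_CENTER"
)
PR_MIDLINE_LANDMARK <- "SACRAL_ENDPLATE_CENTER"
PR_BILATERAL_LANDMARKS <- setdiff(PR_LANDMARKS, PR_MIDLINE_LANDMARK)

PR_COMPONENTS <- c(
  "TRANS_X", "TRANS_Y", "TRANS_Z",
  "ROT_SAGITTAL", "ROT_AXIAL", "ROT_CORONAL"
)
PR_TRANSLATIONS <- PR_COMPONENTS[1:3]
PR_ROTATIONS <- PR_COMPONENTS[4:6]

## Each standardized view is an orthographic projection plane: the inlet
## radiograph is the X/Z plane (drops Y), the outlet radiograph the X/Y
## plane (drops Z), and the AP film is idealized as a second X/Y projection
## distinguished from the outlet only by its landmark set and the component
## it detects.
PR_VIEW_AXES <- list(
  AP     = list(horizontal = "X", vertical = "Y", dropped = "Z"),
  INLET  = list(horizontal = "X", vertical = "Z", dropped = "Y"),
  OUTLET = list(horizontal = "X", vertical = "Y", dropped = "Z")
)

## Landmark catalog per view (order-stable).
PR_VIEW_LANDMARKS <- list(
  AP     = c("ASIS", "ISCHIAL_TUBEROSITY"),
  INLET  = c("ASIS", "ANTERIOR_SI_JOINT_ILIAC", "SACRAL_ENDPLATE_CENTER"),
  OUTLET = c("SUPERIOR_ILIAC_WING", "ISCHIAL_TUBEROSITY", "ASIS",
             "SACRAL_ENDPLATE_CENTER")
)

## Which displacement components each view can detect.  Rotations are named
## anatomically (sagittal = flexion/extension, axial = internal/external,
## coronal = abduction/adduction) rather than by rotation axis.
PR_VIEW_COMPONENTS <- list(
  AP     = "ROT_SAGITTAL",
  INLET  = c("TRANS_X", "TRANS_Z", "ROT_AXIAL"),
  OUTLET = c("TRANS_Y", "ROT_CORONAL")
)

## Designated rotation-measurement segment per view (from -> to).
PR_VIEW_SEGMENT <- list(
  AP     = c("ASIS", "ISCHIAL_TUBEROSITY"),
  INLET  = c("ASIS", "ANTERIOR_SI_JOINT_ILIAC"),
  OUTLET = c("SUPERIOR_ILIAC_WING", "ISCHIAL_TUBEROSITY")
)

## Classed error helper so callers can condition on failure modes.
stop_pelvirad <- function(class, msg, ...) {
  msg <- sprintf(msg, ...)
  cond <- structure(
    class = c(class, "pelvirad_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

check_view <- function(view) {
  if (!is.character(view) || length(view) != 1L || !(view %in% PR_VIEWS)) {
    stop_pelvirad("pelvirad_error_view",
                  "unknown view '%s'; expected one of %s",
                  paste(as.character(view), collapse = ","),
                  paste(PR_VIEWS, collapse = ", "))
  }
  view
}

#' Describe a standardized radiographic view
#'
#' Returns the projection-plane definition of one of the three standardized
#' pelvic views: which world axis runs horizontally and vertically in the
#' film, and which axis the orthographic projection drops.
#'
#' @param name One of `"AP"`, `"INLET"`, `"OUTLET"`.
#' @return A list with elements `name`, `horizontal_axis`, `vertical_axis`,
#'   `dropped_axis` (axis names `"X"`, `"Y"`, `"Z"`).
#' @examples
#' view("INLET")$dropped_axis  # "Y"
#' @export
view <- function(name) {
  check_view(name)
  ax <- PR_VIEW_AXES[[name]]
  list(
    name = name,
    horizontal_axis = ax$horizontal,
    vertical_axis = ax$vertical,
    dropped_axis = ax$dropped
  )
}

#' Landmarks required on a view
#'
#' The representative anatomical landmarks that must be annotated on each
#' standardized view before the deformity can be measured.
#'
#' @param view View name (`"AP"`, `"INLET"`, `"OUTLET"`).
#' @return Character vector of landmark identifiers, order-stable.
#' @examples
#' required_landmarks("AP")
#' @export
required_landmarks <- function(view) {
  check_view(view)
  PR_VIEW_LANDMARKS[[view]]
}

#' Displacement components detectable on a view
#'
#' Each of the six basic displacement patterns (three translations, three
#' rotations) is read off exactly one view: the inlet film shows the
#' mediolateral and anteroposterior translations plus the axial
#' (internal/external) rotation; the outlet film shows the craniocaudal
#' translation plus the coronal (abduction/adduction) rotation; the AP film
#' shows the sagittal (flexion/extension) rotation.
#'
#' @param view View name.
#' @return Character vector of component identifiers.
#' @examples
#' detectable_components("OUTLET")
#' @export
detectable_components <- function(view) {
  check_view(view)
  PR_VIEW_COMPONENTS[[view]]
}

pr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pelvirad")
  if (!nzchar(path)) {
    ## during in-source development (pkgload) system.file still resolves;
    ## a missing fixture is a packaging error
    stop_pelvirad("pelvirad_error_fixture", "fixture '%s' not found", file)
  }
  path
}

pr_cache <- new.env(parent = emptyenv())

#' Sign-to-direction conventions
#'
#' The mapping from the sign of a measured world-axis offset to its
#' anatomical direction label, given which hemipelvis is injured. Shipped
#' as a data table (not code) so the conventions are auditable: e.g. a
#' positive X offset of a LEFT hemipelvis is `lateral`, of a RIGHT
#' hemipelvis `medial`; positive sagittal rotation is `flexion` for either
#' side.
#'
#' @return A data.frame with columns `component`, `injured_side`, `sign`
#'   (`"+"` or `"-"`), `label`.
#' @export
direction_conventions <- function() {
  if (is.null(pr_cache$directions)) {
    pr_cache$directions <- utils::read.csv(
      pr_extdata("direction_conventions.csv"),
      stringsAsFactors = FALSE
    )
  }
  pr_cache$directions
}

direction_label <- function(component, injured_side, value) {
  tab <- direction_conventions()
  sgn <- if (value >= 0) "+" else "-"
  hit <- tab$component == component & tab$injured_side == injured_side &
    tab$sign == sgn
  if (!any(hit)) {
    stop_pelvirad("pelvirad_error_convention",
                  "no direction convention for %s/%s/%s",
                  component, injured_side, sgn)
  }
  tab$label[hit][1L]
}

opposite_side <- function(side) {
  switch(side,
         LEFT = "RIGHT",
         RIGHT = "LEFT",
         stop_pelvirad("pelvirad_error_side",
                       "side '%s' has no opposite", side))
}

check_injured_side <- function(side) {
  if (!is.character(side) || length(side) != 1L ||
      !(side %in% c("LEFT", "RIGHT"))) {
    stop_pelvirad("pelvirad_error_side",
                  "injured side must be LEFT or RIGHT, got '%s'",
                  paste(as.character(side), collapse = ","))
  }
  side
}
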