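#' Construct a 3D pelvic landmark template
#'
#' A template holds the 3D positions (mm, pelvis-specific frame) of the
#' four bilateral landmarks on both hemipelves plus the midline sacral
#' endplate landmark.
#'
#' @param df data.frame with columns `landmark`, `side`, `x`, `y`, `z`.
#' @param version character tag identifying the coordinate fixture.
#' @return An object of class `pelvis_template` (a data.frame).
#' @export
pelvis_template <- function(df, version = "custom") {
  need <- c("landmark", "side", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_pelvirad("pelvirad_error_schema",
                  "template needs columns %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(df$landmark, PR_LANDMARKS)
  if (length(bad)) {
    stop_pelvirad("pelvirad_error_unknown_landmark",
                  "unknown landmark(s): %s", paste(bad, collapse = ", "))
  }
  for (lm in PR_BILATERAL_LANDMARKS) {
    for (sd in c("LEFT", "RIGHT")) {
      if (sum(df$landmark == lm & df$side == sd) != 1L) {
        stop_pelvirad("pelvirad_error_missing_landmark",
                      "template must contain %s/%s exactly once", lm, sd)
      }
    }
  }
  if (sum(df$landmark == PR_MIDLINE_LANDMARK & df$side == "MIDLINE") != 1L) {
    stop_pelvirad("pelvirad_error_missing_landmark",
                  "template must contain %s/MIDLINE exactly once",
                  PR_MIDLINE_LANDMARK)
  }
  df <- df[, need]
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y); df$z <- as.numeric(df$z)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z))) {
    stop_pelvirad("pelvirad_error_schema",
                  "template coordinates must be finite numbers")
  }
  df <- df[order(match(df$landmark, PR_LANDMARKS), match(df$side, PR_SIDES)), ]
  rownames(df) <- NULL
  structure(df, class = c("pelvis_template", "data.frame"),
            version = version)
}

#' Default bilaterally symmetric landmark template
#'
#' Anatomically plausible adult-scale coordinates, shipped as a versioned
#' CSV fixture so that every downstream result is pinned to a concrete,
#' reproducible landmark geometry (the bony landmarks themselves carry no
#' canonical coordinates). Bilateral landmarks are exact mirror images
#' about the midsagittal plane X = 0; the sacral endplate landmark sits at
#' the origin.
#'
#' @param version fixture version tag (currently `"v1"`).
#' @return A `pelvis_template`.
#' @examples
#' tpl <- default_template()
#' subset(tpl, landmark == "ASIS")
#' @export
default_template <- function(version = "v1") {
  key <- paste0("template_", version)
  if (is.null(pr_cache[[key]])) {
    df <- utils::read.csv(pr_extdata(sprintf("pelvis_template_%s.csv", version)),
                          stringsAsFactors = FALSE)
    names(df) <- sub("_mm$", "", names(df))
    pr_cache[[key]] <- pelvis_template(df, version = version)
  }
  pr_cache[[key]]
}

## landmark coordinate matrix for one side (rows named by landmark)
template_points <- function(template, side, landmarks = NULL) {
  rows <- template[template$side == side, , drop = FALSE]
  if (!is.null(landmarks)) {
    rows <- rows[match(landmarks, rows$landmark), , drop = FALSE]
  }
  m <- as.matrix(rows[, c("x", "y", "z")])
  rownames(m) <- rows$landmark
  m
}

## centroid of the injured hemipelvis's four bilateral landmarks: the
## default rotation center of a rigid displacement
hemipelvis_centroid <- function(template, side) {
  colMeans(template_points(template, side, PR_BILATERAL_LANDMARKS))
}
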