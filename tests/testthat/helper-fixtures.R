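# Fixtures are built in code at test time; nothing binary ships with the
# package sources.

pr_components <- c("TRANS_X", "TRANS_Y", "TRANS_Z",
                   "ROT_SAGITTAL", "ROT_AXIAL", "ROT_CORONAL")
pr_translations <- pr_components[1:3]
pr_rotations <- pr_components[4:6]

# rigid_displacement with a single named component set
single_component_displacement <- function(component, value,
                                          injured_side = "LEFT") {
  arg <- switch(component,
                TRANS_X = "tx", TRANS_Y = "ty", TRANS_Z = "tz",
                ROT_SAGITTAL = "sagittal", ROT_AXIAL = "axial",
                ROT_CORONAL = "coronal")
  args <- list(injured_side = injured_side)
  args[[arg]] <- value
  do.call(rigid_displacement, args)
}

pattern_categories <- function(pattern) {
  out <- ifelse(pattern$status == "PRESENT", pattern$direction, "absent")
  stats::setNames(out, pattern$component)
}

# independent homogeneous-matrix oracle for the rigid transform:
# T = translate(t) . translate(c) . Rx(s) Ry(a) Rz(c) . translate(-c)
homogeneous_oracle <- function(points, translation, rot_deg, center) {
  deg2rad <- pi / 180
  rx <- function(a) {
    a <- a * deg2rad
    rbind(c(1, 0, 0, 0), c(0, cos(a), -sin(a), 0),
          c(0, sin(a), cos(a), 0), c(0, 0, 0, 1))
  }
  ry <- function(a) {
    a <- a * deg2rad
    rbind(c(cos(a), 0, sin(a), 0), c(0, 1, 0, 0),
          c(-sin(a), 0, cos(a), 0), c(0, 0, 0, 1))
  }
  rz <- function(a) {
    a <- a * deg2rad
    rbind(c(cos(a), -sin(a), 0, 0), c(sin(a), cos(a), 0, 0),
          c(0, 0, 1, 0), c(0, 0, 0, 1))
  }
  tr <- function(v) rbind(c(1, 0, 0, v[1]), c(0, 1, 0, v[2]),
                          c(0, 0, 1, v[3]), c(0, 0, 0, 1))
  M <- tr(translation) %*% tr(center) %*%
    rx(rot_deg[1]) %*% ry(rot_deg[2]) %*% rz(rot_deg[3]) %*% tr(-center)
  h <- cbind(points, 1) %*% t(M)
  h[, 1:3, drop = FALSE]
}

# minimal explicit-VR little-endian DICOM part-10 file with PixelSpacing
write_minimal_dicom <- function(path, row_mm, col_mm = row_mm) {
  uint16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  uint32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                 (x %/% 65536) %% 256, x %/% 16777216))
  # UI values are NUL-padded to even length, DS values space-padded
  ui_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0L))
    r
  }
  ds_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  }
  short_elem <- function(group, elem, vr, value) {
    c(uint16(group), uint16(elem), charToRaw(vr),
      uint16(length(value)), value)
  }
  ts <- ui_raw("1.2.840.10008.1.2.1")
  sop <- ui_raw("1.2.840.10008.5.1.4.1.1.7")
  meta <- c(
    short_elem(2L, 2L, "UI", sop),    # media storage SOP class
    short_elem(2L, 16L, "UI", ts)     # transfer syntax
  )
  spacing <- ds_raw(sprintf("%g\\%g", row_mm, col_mm))
  body <- c(
    short_elem(8L, 96L, "US", uint16(1L)),        # (0008,0060)-ish filler
    short_elem(40L, 16L, "US", uint16(128L)),     # rows
    short_elem(40L, 17L, "US", uint16(128L)),     # columns
    short_elem(40L, 48L, "DS", spacing)           # PixelSpacing (0028,0030)
  )
  raw <- c(
    raw(128L), charToRaw("DICM"),
    short_elem(2L, 0L, "UL", uint32(length(meta))), # file meta group length
    meta, body
  )
  writeBin(raw, path)
  invisible(path)
}

# long-format random rating table with some association to a gold standard
random_rating_table <- function(n_obs, n_cases, categories, gold_prob,
                                seed) {
  set.seed(seed)
  gold <- sample(categories, n_cases, replace = TRUE)
  rows <- do.call(rbind, lapply(seq_len(n_obs), function(o) {
    rated <- ifelse(runif(n_cases) < gold_prob, gold,
                    sample(categories, n_cases, replace = TRUE))
    data.frame(observer = sprintf("obs%d", o),
               case = sprintf("case%03d", seq_len(n_cases)),
               component = "COMP", category = rated,
               stringsAsFactors = FALSE)
  }))
  list(table = rating_table(rows),
       gold = data.frame(case = sprintf("case%03d", seq_len(n_cases)),
                         component = "COMP", category = gold,
                         stringsAsFactors = FALSE))
}

# brute-force kappa oracle: direct counting loops, no shared code path
brute_force_kappa <- function(a, b) {
  n <- length(a)
  po <- 0
  for (i in seq_len(n)) if (a[i] == b[i]) po <- po + 1 / n
  lev <- unique(c(a, b))
  pe <- 0
  for (l in lev) {
    pa <- 0; pb <- 0
    for (i in seq_len(n)) {
      if (a[i] == l) pa <- pa + 1 / n
      if (b[i] == l) pb <- pb + 1 / n
    }
    pe <- pe + pa * pb
  }
  (po - pe) / (1 - pe)
}
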