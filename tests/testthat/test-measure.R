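noise_free_case <- function(component, value, side = "LEFT",
                            mm_per_px = 1) {
  make_case(single_component_displacement(component, value, side),
            mm_per_px = mm_per_px)
}

test_that("midline reference sits on the sacral landmark and tracks shifts", {
  inlet <- project(default_template(), "INLET", 1, injured_side = "LEFT")
  expect_equal(midline_reference(inlet), 0)

  shifted <- inlet
  shifted$landmarks$x <- shifted$landmarks$x + 7
  expect_equal(midline_reference(shifted), 7)

  # AP has no midline landmark: vertical bisector of the ischial tuberosities
  ap <- project(default_template(), "AP", 1, injured_side = "LEFT")
  expect_equal(midline_reference(ap), 0)
  ap$landmarks$x <- ap$landmarks$x + 3
  expect_equal(midline_reference(ap), 3)

  # neither midline landmark nor bilateral fallback
  broken <- inlet
  broken$landmarks <- broken$landmarks[broken$landmarks$side != "MIDLINE", ]
  expect_error(midline_reference(broken), class = "pelvirad_error_midline")
})

test_that("midline estimate under jitter is unbiased with the jitter's spread", {
  # landmark jitter sd 0.5 mm propagates directly to the sacral reference:
  # the midline error should be centered on 0 with SD about 0.5 mm
  inlet <- project(default_template(), "INLET", 0.5, injured_side = "LEFT")
  errs <- vapply(seq_len(200), function(i) {
    j <- add_observer_jitter(inlet, 0.5, seed = 5000 + i)
    midline_reference(j) * j$mm_per_px
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.15)
  expect_gt(sd(errs), 0.35)
  expect_lt(sd(errs), 0.65)
})

test_that("mirroring the intact side reproduces the injured side when symmetric", {
  for (v in c("AP", "INLET", "OUTLET")) {
    ann <- project(default_template(), v, 1, injured_side = "LEFT")
    mir <- mirror_intact(ann)
    lm <- ann$landmarks
    for (i in seq_len(nrow(mir))) {
      inj <- lm[lm$landmark == mir$landmark[i] & lm$side == "LEFT", ]
      expect_lt(abs(mir$x[i] - inj$x), 1e-9)
      expect_lt(abs(mir$y[i] - inj$y), 1e-9)
    }
  }
})

test_that("mirroring is an involution", {
  ann <- project(default_template(), "OUTLET", 0.5, injured_side = "LEFT")
  line <- midline_reference(ann)
  mir <- mirror_intact(ann, line)
  # reflecting the mirrored coordinates again returns the intact originals
  back_x <- 2 * line - mir$x
  lm <- ann$landmarks
  for (i in seq_len(nrow(mir))) {
    orig <- lm[lm$landmark == mir$landmark[i] & lm$side == "RIGHT", ]
    expect_identical(back_x[i], orig$x)
    expect_identical(mir$y[i], orig$y)
  }
})

test_that("mirrored-intact vs injured gap equals the applied translation", {
  cs <- noise_free_case("TRANS_X", 10)
  inlet <- cs$views$INLET
  mir <- mirror_intact(inlet)
  lm <- inlet$landmarks
  gaps <- vapply(seq_len(nrow(mir)), function(i) {
    inj <- lm[lm$landmark == mir$landmark[i] & lm$side == "LEFT", ]
    (inj$x - mir$x[i]) * inlet$mm_per_px
  }, numeric(1))
  expect_equal(gaps, rep(10, length(gaps)), tolerance = 1e-9)
  # missing intact landmark is reported by name
  broken <- inlet
  broken$landmarks <- broken$landmarks[
    !(broken$landmarks$landmark == "ASIS" & broken$landmarks$side == "RIGHT"), ]
  expect_error(mirror_intact(broken), "ASIS",
               class = "pelvirad_error_missing_landmark")
})

test_that("per-view offsets vanish on an undisplaced noise-free case", {
  cs <- make_case(rigid_displacement())
  for (v in c("AP", "INLET", "OUTLET")) {
    m <- measure_view(cs$views[[v]])
    expect_lt(max(abs(m$offsets)), 1e-9)
  }
})

test_that("per-view offsets recover single-component ground truth", {
  # anteroposterior translation read off the inlet view
  m <- measure_view(noise_free_case("TRANS_Z", 8)$views$INLET)
  expect_equal(unname(m$offsets[["TRANS_Z"]]), 8, tolerance = 0.1)
  expect_lt(abs(m$offsets[["TRANS_X"]]), 1e-6)

  # pure axial rotation read off the inlet view, centroid rotation center
  m2 <- measure_view(noise_free_case("ROT_AXIAL", 10)$views$INLET)
  expect_equal(unname(m2$offsets[["ROT_AXIAL"]]), 10, tolerance = 1)
  expect_lt(abs(m2$offsets[["TRANS_X"]]), 5)
  expect_lt(abs(m2$offsets[["TRANS_Z"]]), 5)

  # degenerate segment is a named error
  bad <- noise_free_case("TRANS_X", 0)$views$INLET
  lm <- bad$landmarks
  asis <- lm$landmark == "ASIS" & lm$side == "RIGHT"
  sij <- lm$landmark == "ANTERIOR_SI_JOINT_ILIAC" & lm$side == "RIGHT"
  lm[sij, c("x", "y")] <- lm[asis, c("x", "y")]
  bad$landmarks <- lm
  expect_error(measure_view(bad), class = "pelvirad_error_degenerate")
})

test_that("classification applies the threshold rule with tie = PRESENT", {
  mk <- function(view, offsets) {
    structure(list(view = view, offsets = offsets, injured_side = "LEFT",
                   scale = 1), class = "view_measurement")
  }
  zero <- list(
    mk("AP", c(ROT_SAGITTAL = 0)),
    mk("INLET", c(TRANS_X = 0, TRANS_Z = 0, ROT_AXIAL = 0)),
    mk("OUTLET", c(TRANS_Y = 0, ROT_CORONAL = 0))
  )
  pat <- classify(zero, thresholds())
  expect_true(all(pat$status == "ABSENT"))

  one <- list(
    mk("AP", c(ROT_SAGITTAL = 0)),
    mk("INLET", c(TRANS_X = 0, TRANS_Z = 0, ROT_AXIAL = 0)),
    mk("OUTLET", c(TRANS_Y = 10, ROT_CORONAL = 0))
  )
  pat1 <- classify(one, thresholds())
  cats <- pattern_categories(pat1)
  expect_equal(unname(cats[["TRANS_Y"]]), "cephalad")
  expect_equal(sum(cats != "absent"), 1L)

  # exactly at threshold: PRESENT
  tie <- list(
    mk("AP", c(ROT_SAGITTAL = 5)),
    mk("INLET", c(TRANS_X = 0, TRANS_Z = 0, ROT_AXIAL = 0)),
    mk("OUTLET", c(TRANS_Y = 0, ROT_CORONAL = 0))
  )
  expect_equal(unname(pattern_categories(classify(tie))[["ROT_SAGITTAL"]]),
               "flexion")

  # missing view / conflicting sides are named errors
  expect_error(classify(zero[1:2]), class = "pelvirad_error_missing_view")
  conflicted <- zero
  conflicted[[2]]$injured_side <- "RIGHT"
  expect_error(classify(conflicted), class = "pelvirad_error_inconsistent")
})

test_that("the five-component clinical-style pattern serializes to the per-view report", {
  d <- rigid_displacement(tx = -10, ty = 10, tz = 10, sagittal = -10,
                          axial = -10, injured_side = "LEFT")
  pat <- measure_case(make_case(d))
  expect_equal(
    format_pattern(pat),
    "extension (AP); cephalad (outlet); medial, anterior, internal rotation (inlet)"
  )
  # the sixth component stays absent
  expect_equal(unname(pattern_categories(pat)[["ROT_CORONAL"]]), "absent")
  expect_identical(pattern_categories(pat),
                   pattern_categories(truth_pattern(d)))
})

test_that("all 12 direction-resolved single-component cases are recovered exactly", {
  for (side in c("LEFT", "RIGHT")) {
    for (comp in pr_components) {
      for (sgn in c(1, -1)) {
        thrv <- if (comp %in% pr_translations) 5 else 5
        cs <- noise_free_case(comp, sgn * 2 * thrv, side)
        pat <- measure_case(cs)
        expect_identical(pattern_categories(pat),
                         pattern_categories(cs$truth),
                         info = sprintf("%s %s %+d", side, comp, sgn))
        expect_equal(sum(pat$status == "PRESENT"), 1L)
      }
    }
  }
})

test_that("sub-threshold displacements yield the empty pattern", {
  for (comp in pr_components) {
    for (sgn in c(1, -1)) {
      cs <- noise_free_case(comp, sgn * 2.5) # 0.5x the 5 mm / 5 deg threshold
      pat <- measure_case(cs)
      expect_true(all(pat$status == "ABSENT"),
                  info = sprintf("%s %+d", comp, sgn))
    }
  }
})

test_that("translation-only cases flag no rotation component", {
  set.seed(1203)
  for (i in 1:25) {
    d <- rigid_displacement(tx = runif(1, -25, 25), ty = runif(1, -25, 25),
                            tz = runif(1, -25, 25),
                            injured_side = sample(c("LEFT", "RIGHT"), 1))
    pat <- measure_case(make_case(d))
    rot <- pat[pat$component %in% pr_rotations, ]
    expect_true(all(rot$status == "ABSENT"))
    expect_identical(pattern_categories(pat),
                     pattern_categories(truth_pattern(d)))
  }
})

test_that("classification is equivariant under left/right mirroring", {
  set.seed(88)
  for (i in 1:20) {
    tx <- runif(1, -20, 20); ty <- runif(1, -20, 20); tz <- runif(1, -20, 20)
    s <- runif(1, -15, 15); a <- runif(1, -15, 15); co <- runif(1, -15, 15)
    left <- make_case(rigid_displacement(tx, ty, tz, s, a, co,
                                         injured_side = "LEFT"))
    # the anatomically identical injury of the RIGHT hemipelvis
    right <- make_case(rigid_displacement(-tx, ty, tz, s, -a, -co,
                                          injured_side = "RIGHT"))
    pl <- pattern_categories(measure_case(left))
    pr <- pattern_categories(measure_case(right))
    expect_identical(pl, pr)
  }
})

test_that("classification is invariant to joint pixel/calibration rescaling", {
  d <- rigid_displacement(tx = -8, sagittal = 9, injured_side = "RIGHT")
  base <- make_case(d, mm_per_px = 1)
  rescaled <- base
  for (v in names(rescaled$views)) {
    ann <- rescaled$views[[v]]
    ann$landmarks$x <- ann$landmarks$x * 4
    ann$landmarks$y <- ann$landmarks$y * 4
    ann$mm_per_px <- ann$mm_per_px / 4
    rescaled$views[[v]] <- ann
  }
  p1 <- measure_case(base)
  p2 <- measure_case(rescaled)
  expect_identical(pattern_categories(p1), pattern_categories(p2))
  expect_equal(attr(p1, "offsets"), attr(p2, "offsets"), tolerance = 1e-9)
})

test_that("pattern recovery stays above 95% under 1 mm observer jitter", {
  set.seed(31415)
  n <- 200
  correct <- 0L
  for (i in seq_len(n)) {
    comp <- pr_components[(i - 1L) %% 6L + 1L]
    sgn <- if (i %% 2L) 1 else -1
    mag <- runif(1, 2, 4) * 5 # >= 2x the threshold
    side <- sample(c("LEFT", "RIGHT"), 1)
    cs <- make_case(single_component_displacement(comp, sgn * mag, side),
                    sigma_mm = 1, seed = 31415 + i, mm_per_px = 0.5)
    pat <- measure_case(cs)
    if (identical(pattern_categories(pat), pattern_categories(cs$truth))) {
      correct <- correct + 1L
    }
  }
  expect_gte(correct / n, 0.95)
})
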