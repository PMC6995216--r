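test_that("kappa basics: perfect agreement, chance agreement, symmetry, range", {
  expect_equal(cohens_kappa(c("A", "B", "A", "C"), c("A", "B", "A", "C"))$kappa, 1)

  # hand-computable 2x2 table: po = 0.5, pe = 0.5 -> kappa 0
  k0 <- cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))
  expect_equal(k0$kappa, 0)
  expect_equal(k0$po, 0.5)
  expect_equal(k0$pe, 0.5)

  # perfect disagreement with balanced binary marginals: kappa = -1
  a <- rep(c("yes", "no"), 5)
  expect_equal(cohens_kappa(a, rev(a))$kappa, -1)

  set.seed(7)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- sample(letters[1:4], n, replace = TRUE)
    y <- sample(letters[1:4], n, replace = TRUE)
    k <- tryCatch(cohens_kappa(x, y), pelvirad_error = function(e) NULL)
    if (is.null(k)) next
    expect_gte(k$kappa, -1 - 1e-12)
    expect_lte(k$kappa, 1 + 1e-12)
    expect_equal(k$kappa, cohens_kappa(y, x)$kappa)  # symmetric
    expect_equal(unname(k$ci95),
                 k$kappa + c(-1, 1) * qnorm(0.975) * k$se)
  }

  # independent uniform ratings: kappa near zero
  set.seed(123)
  x <- sample(LETTERS[1:4], 10000, replace = TRUE)
  y <- sample(LETTERS[1:4], 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)$kappa), 0.05)

  # degenerate and malformed inputs
  expect_equal(cohens_kappa(c("A", "A"), c("A", "A"))$kappa, 1)
  expect_error(cohens_kappa(c("A", "B"), c("A")),
               class = "pelvirad_error_length")
  expect_error(cohens_kappa("A", "A"), class = "pelvirad_error_length")
})

test_that("kappa matches a brute-force contingency oracle to 1e-12", {
  set.seed(2718)
  checked <- 0L
  while (checked < 1000L) {
    n <- sample(5:40, 1)
    m <- sample(2:5, 1)
    x <- sample(letters[1:m], n, replace = TRUE)
    y <- ifelse(runif(n) < 0.5, x, sample(letters[1:m], n, replace = TRUE))
    ko <- tryCatch(cohens_kappa(x, y), pelvirad_error = function(e) NULL)
    if (is.null(ko)) next # constant-table degenerate draw
    expect_lt(abs(ko$kappa - brute_force_kappa(x, y)), 1e-12)
    checked <- checked + 1L
  }
})

test_that("Landis-Koch mapping reproduces the published bands and boundaries", {
  expect_equal(landis_koch_band(0.853), "almost perfect agreement")
  expect_equal(landis_koch_band(-0.1), "no agreement")
  expect_equal(landis_koch_band(0), "slight agreement")
  expect_equal(landis_koch_band(0.20), "slight agreement")
  expect_equal(landis_koch_band(0.21), "fair agreement")
  expect_equal(landis_koch_band(0.40), "fair agreement")
  expect_equal(landis_koch_band(0.41), "moderate agreement")
  expect_equal(landis_koch_band(0.60), "moderate agreement")
  expect_equal(landis_koch_band(0.61), "substantial agreement")
  expect_equal(landis_koch_band(0.80), "substantial agreement")
  expect_equal(landis_koch_band(0.81), "almost perfect agreement")
  expect_equal(landis_koch_band(1), "almost perfect agreement")
  expect_equal(landis_koch_band(-1), "no agreement")
  expect_error(landis_koch_band(1.2), class = "pelvirad_error_kappa_range")
  expect_error(landis_koch_band(-1.2), class = "pelvirad_error_kappa_range")

  # total piecewise-constant function over a fine grid
  grid <- seq(-1, 1, by = 0.001)
  bands <- vapply(grid, landis_koch_band, character(1))
  expect_equal(sort(unique(bands)), sort(c(
    "no agreement", "slight agreement", "fair agreement",
    "moderate agreement", "substantial agreement",
    "almost perfect agreement"
  )))
  # band is non-decreasing in kappa
  ord <- match(bands, c("no agreement", "slight agreement", "fair agreement",
                        "moderate agreement", "substantial agreement",
                        "almost perfect agreement"))
  expect_true(all(diff(ord) >= 0))
})

test_that("multi-observer aggregation is the mean of pairwise kappas", {
  # four identical observers -> 1.0
  base <- data.frame(
    case = rep(sprintf("c%02d", 1:10), each = 6),
    component = rep(pr_components, 10),
    category = rep(c("absent", "cephalad", "absent", "flexion", "absent",
                     "absent"), 10),
    stringsAsFactors = FALSE
  )
  tab <- rating_table(do.call(rbind, lapply(1:4, function(o) {
    cbind(observer = sprintf("obs%d", o), base)
  })))
  expect_equal(overall_kappa(tab)$kappa, 1)

  # mean over the observer pairs equals direct arithmetic
  set.seed(11)
  tab3 <- rating_table(do.call(rbind, lapply(1:3, function(o) {
    b <- base
    flip <- runif(nrow(b)) < 0.15
    b$category[flip] <- sample(c("absent", "caudad"), sum(flip),
                               replace = TRUE)
    cbind(observer = sprintf("obs%d", o), b)
  })))
  res <- overall_kappa(tab3)
  pair_ks <- vapply(res$details$pairs, `[[`, numeric(1), "kappa")
  expect_length(pair_ks, 3L) # observer pairs (1,2), (1,3), (2,3)
  expect_equal(res$kappa, mean(pair_ks))

  # restricting to a movement type partitions the stream
  kt <- overall_kappa(tab3, components = pr_translations)
  kr <- overall_kappa(tab3, components = pr_rotations)
  expect_s3_class(kt, "kappa_result")
  expect_s3_class(kr, "kappa_result")
  expect_equal(kt$n, 30L) # 10 cases x 3 translational components
  expect_equal(kr$n, 30L)

  # Fleiss' kappa option agrees at perfect agreement
  expect_equal(overall_kappa(tab, method = "fleiss")$kappa, 1)
})

test_that("validity kappa scores observers against the gold standard", {
  gold <- data.frame(case = sprintf("c%02d", 1:10), component = "COMP",
                     category = rep(c("absent", "cephalad"), 5),
                     stringsAsFactors = FALSE)
  perfect <- rating_table(do.call(rbind, lapply(1:3, function(o) {
    data.frame(observer = sprintf("obs%d", o), case = gold$case,
               component = "COMP", category = gold$category,
               stringsAsFactors = FALSE)
  })))
  v <- validity_kappa(perfect, gold)
  expect_true(all(vapply(v$per_observer, `[[`, numeric(1), "kappa") == 1))
  expect_equal(v$pooled$kappa, 1)

  # total disagreement on a balanced two-category gold: kappa -1
  wrong <- rating_table(data.frame(
    observer = "obs1", case = gold$case, component = "COMP",
    category = ifelse(gold$category == "absent", "cephalad", "absent"),
    stringsAsFactors = FALSE
  ))
  expect_equal(validity_kappa(wrong, gold)$per_observer$obs1$kappa, -1)

  # missing gold entry is a named error
  expect_error(validity_kappa(perfect, gold[-1, ]),
               class = "pelvirad_error_missing_gold")
})

test_that("pooled validity kappa lies within the per-observer range", {
  for (seed in 1:100) {
    sim <- random_rating_table(n_obs = 3, n_cases = 40,
                               categories = c("absent", "cephalad", "caudad"),
                               gold_prob = 0.7, seed = seed)
    v <- validity_kappa(sim$table, sim$gold)
    ks <- vapply(v$per_observer, `[[`, numeric(1), "kappa")
    expect_gte(v$pooled$kappa, min(ks) - 1e-9)
    expect_lte(v$pooled$kappa, max(ks) + 1e-9)
  }
})

test_that("confidence-interval width shrinks as 1/sqrt(n)", {
  set.seed(606)
  ns <- c(50, 100, 200, 400, 800, 1600)
  widths <- vapply(ns, function(n) {
    mean(vapply(1:30, function(r) {
      gold <- sample(c("A", "B", "C"), n, replace = TRUE)
      rated <- ifelse(runif(n) < 0.75, gold,
                      sample(c("A", "B", "C"), n, replace = TRUE))
      k <- cohens_kappa(gold, rated)
      unname(diff(k$ci95))
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(ns)))[[2]]
  expect_lt(abs(slope - (-0.5)), 0.15 * 0.5)
})
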