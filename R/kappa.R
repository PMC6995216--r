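## Cohen's kappa machinery: chance-corrected agreement, asymptotic SE and
## 95% CI, Landis-Koch interpretation, multi-observer aggregation, and
## validity against a gold standard.

PR_LANDIS_KOCH <- c(
  "no agreement", "slight agreement", "fair agreement",
  "moderate agreement", "substantial agreement", "almost perfect agreement"
)

#' Landis-Koch interpretation band for a kappa value
#'
#' Maps kappa onto the conventional verbal strength-of-agreement bands:
#' below 0 no agreement, 0.00-0.20 slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect. Band upper
#' bounds are inclusive, so 0.20 is "slight" and 0.21 (anything above
#' 0.20) is "fair".
#'
#' @param kappa numeric in \[-1, 1\].
#' @return The band label (character).
#' @examples
#' landis_koch_band(0.853)
#' @export
landis_koch_band <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < -1 - 1e-9 || kappa > 1 + 1e-9) {
    stop_pelvirad("pelvirad_error_kappa_range",
                  "kappa must be a number in [-1, 1]")
  }
  if (kappa < 0) return(PR_LANDIS_KOCH[1L])
  if (kappa <= 0.20) return(PR_LANDIS_KOCH[2L])
  if (kappa <= 0.40) return(PR_LANDIS_KOCH[3L])
  if (kappa <= 0.60) return(PR_LANDIS_KOCH[4L])
  if (kappa <= 0.80) return(PR_LANDIS_KOCH[5L])
  PR_LANDIS_KOCH[6L]
}

kappa_result <- function(kappa, se, n, po = NA_real_, pe = NA_real_,
                         details = NULL) {
  ci <- kappa + c(-1, 1) * stats::qnorm(0.975) * se
  structure(
    list(kappa = kappa, se = se, ci95 = c(lower = ci[1L], upper = ci[2L]),
         band = landis_koch_band(min(1, max(-1, kappa))),
         n = n, po = po, pe = pe, details = details),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa = %.3f (SE %.3f, 95%% CI %.3f-%.3f), %s; n = %d\n",
              x$kappa, x$se, x$ci95[["lower"]], x$ci95[["upper"]],
              x$band, x$n))
  invisible(x)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` between two
#' paired categorical rating vectors, with the large-sample standard
#' error of Fleiss, Cohen & Everitt (1969) and the Wald 95% confidence
#' interval `kappa +/- 1.96 se`. If both raters are constant and
#' identical (chance agreement 1), kappa is defined as 1 with SE 0.
#'
#' @param a,b equal-length categorical vectors (character or factor),
#'   at least 2 items.
#' @return A `kappa_result`: `kappa`, `se`, `ci95`, Landis-Koch `band`,
#'   `n`, observed (`po`) and chance (`pe`) agreement.
#' @examples
#' cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))  # kappa 0
#' @export
cohens_kappa <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) {
    stop_pelvirad("pelvirad_error_length",
                  "rating vectors differ in length (%d vs %d)",
                  length(a), length(b))
  }
  n <- length(a)
  if (n < 2L) {
    stop_pelvirad("pelvirad_error_length",
                  "need at least 2 paired ratings, got %d", n)
  }
  if (anyNA(a) || anyNA(b)) {
    stop_pelvirad("pelvirad_error_schema", "ratings must not contain NA")
  }
  lev <- sort(unique(c(a, b)))
  p <- table(factor(a, levels = lev), factor(b, levels = lev)) / n
  po <- sum(diag(p))
  prow <- rowSums(p)
  pcol <- colSums(p)
  pe <- sum(prow * pcol)
  if (1 - pe < 1e-12) {
    if (1 - po < 1e-12) return(kappa_result(1, 0, n, po = po, pe = pe))
    stop_pelvirad("pelvirad_error_degenerate_kappa",
                  "chance agreement is 1 but raters are not identical")
  }
  k <- (po - pe) / (1 - pe)
  ## Fleiss, Cohen & Everitt (1969) asymptotic SE
  m <- length(lev)
  A <- sum(diag(p) * (1 - (prow + pcol) * (1 - k))^2)
  B <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) B <- B + p[i, j] * (pcol[i] + prow[j])^2
    }
  }
  B <- (1 - k)^2 * B
  C <- (k - pe * (1 - k))^2
  se <- sqrt(max(0, A + B - C)) / ((1 - pe) * sqrt(n))
  kappa_result(k, se, n, po = po, pe = pe)
}

## long rating table -> per-observer vectors in a fixed (case, component)
## order; optionally restricted to a component subset
observer_vectors <- function(table, components = NULL) {
  df <- table
  if (!is.null(components)) df <- df[df$component %in% components, ]
  df <- df[order(df$case, df$component), ]
  split(df$category, df$observer)
}

#' Construct and validate a multi-observer rating table
#'
#' Long-format table of direction-resolved categorical judgments: one row
#' per (observer, case, component). The table must be rectangular — every
#' observer rates every case/component exactly once.
#'
#' @param df data.frame with columns `observer`, `case`, `component`,
#'   `category`.
#' @return A `rating_table` (data.frame).
#' @export
rating_table <- function(df) {
  need <- c("observer", "case", "component", "category")
  if (!all(need %in% names(df))) {
    stop_pelvirad("pelvirad_error_schema",
                  "rating table needs columns %s", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  df[] <- lapply(df, as.character)
  counts <- table(df$observer, paste(df$case, df$component, sep = "\r"))
  if (any(counts != 1L)) {
    stop_pelvirad("pelvirad_error_schema",
                  "rating table is not rectangular: every observer must rate every case/component exactly once")
  }
  structure(df, class = c("rating_table", "data.frame"))
}

#' Multi-observer inter-rater reliability
#'
#' Aggregates agreement across all observer pairs as the mean of the
#' pairwise Cohen's kappas, pooling the components of each case into one
#' categorical stream (both the single overall value and the per-pair
#' results are returned). Fleiss' multi-rater kappa is available
#' as a clearly non-default option.
#'
#' @param table a `rating_table` (or coercible data.frame).
#' @param components optional component subset (e.g. translations only).
#' @param method `"pairwise_cohen"` (default) or `"fleiss"`.
#' @return A `kappa_result`; for the pairwise method `details$pairs` holds
#'   the per-pair results and the SE is the (independence-approximated)
#'   SE of the mean of pairwise kappas.
#' @export
overall_kappa <- function(table, components = NULL,
                          method = c("pairwise_cohen", "fleiss")) {
  method <- match.arg(method)
  if (!inherits(table, "rating_table")) table <- rating_table(table)
  vecs <- observer_vectors(table, components)
  if (length(vecs) < 2L) {
    stop_pelvirad("pelvirad_error_schema", "need at least 2 observers")
  }
  if (method == "fleiss") {
    return(fleiss_kappa(do.call(cbind, vecs)))
  }
  obs <- names(vecs)
  pairs <- utils::combn(obs, 2L, simplify = FALSE)
  res <- lapply(pairs, function(p) cohens_kappa(vecs[[p[1L]]], vecs[[p[2L]]]))
  names(res) <- vapply(pairs, paste, character(1), collapse = " vs ")
  ks <- vapply(res, `[[`, numeric(1), "kappa")
  ses <- vapply(res, `[[`, numeric(1), "se")
  kbar <- mean(ks)
  se <- sqrt(sum(ses^2)) / length(ses)
  kappa_result(kbar, se, n = length(vecs[[1L]]),
               details = list(pairs = res, method = method))
}

#' Fleiss' kappa for multiple raters
#'
#' Standard Fleiss (1971) multi-rater kappa over a subjects-by-raters
#' matrix of categorical ratings, with the Fleiss-Nee-Landis standard
#' error.
#'
#' @param ratings matrix (subjects in rows, raters in columns).
#' @return A `kappa_result`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  N <- nrow(ratings)
  r <- ncol(ratings)
  if (N < 2L || r < 2L) {
    stop_pelvirad("pelvirad_error_schema",
                  "need at least 2 subjects and 2 raters")
  }
  lev <- sort(unique(as.character(ratings)))
  nij <- t(apply(ratings, 1L, function(row) {
    tabulate(factor(as.character(row), levels = lev), nbins = length(lev))
  }))
  pj <- colSums(nij) / (N * r)
  Pi <- (rowSums(nij^2) - r) / (r * (r - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (1 - Pe < 1e-12) {
    if (1 - Pbar < 1e-12) return(kappa_result(1, 0, N, po = Pbar, pe = Pe))
    stop_pelvirad("pelvirad_error_degenerate_kappa",
                  "chance agreement is 1 but raters are not identical")
  }
  k <- (Pbar - Pe) / (1 - Pe)
  se <- sqrt(2 / (N * r * (r - 1))) *
    sqrt(Pe - (2 * r - 3) * Pe^2 + 2 * (r - 2) * sum(pj^3)) / (1 - Pe)
  kappa_result(k, se, N, po = Pbar, pe = Pe,
               details = list(method = "fleiss"))
}

#' Validity of observers against a gold standard
#'
#' Cohen's kappa of each observer against the gold-standard consensus
#' judgment, plus the pooled kappa of all observers' ratings concatenated
#' against the (replicated) gold standard.
#'
#' @param table a `rating_table`.
#' @param gold data.frame with columns `case`, `component`, `category`
#'   covering every (case, component) in the table.
#' @return List with `per_observer` (named list of `kappa_result`) and
#'   `pooled` (a `kappa_result`).
#' @export
validity_kappa <- function(table, gold) {
  if (!inherits(table, "rating_table")) table <- rating_table(table)
  need <- c("case", "component", "category")
  if (!all(need %in% names(gold))) {
    stop_pelvirad("pelvirad_error_schema",
                  "gold standard needs columns %s", paste(need, collapse = ", "))
  }
  gold <- as.data.frame(gold)
  gold[] <- lapply(gold[, need], as.character)
  key <- function(case, component) paste(case, component, sep = "\r")
  gmap <- stats::setNames(gold$category, key(gold$case, gold$component))
  tkeys <- unique(key(table$case, table$component))
  missing <- setdiff(tkeys, names(gmap))
  if (length(missing)) {
    stop_pelvirad("pelvirad_error_missing_gold",
                  "gold standard missing %d (case, component) entr%s, e.g. %s",
                  length(missing), if (length(missing) == 1L) "y" else "ies",
                  sub("\r", " / ", missing[1L]))
  }
  df <- table[order(table$case, table$component), ]
  per <- lapply(split(df, df$observer), function(sub) {
    cohens_kappa(sub$category, unname(gmap[key(sub$case, sub$component)]))
  })
  pooled <- cohens_kappa(df$category, unname(gmap[key(df$case, df$component)]))
  list(per_observer = per, pooled = pooled)
}
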