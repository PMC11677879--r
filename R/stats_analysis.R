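# Rank-based group statistics for interpretable features: Kruskal-Wallis
# test with tie correction, the H-based eta-squared effect size, and Dunn's
# post hoc test with Bonferroni correction.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic over k groups with a chi-squared (k - 1 df)
#' p value. All-identical values give H = 0, p = 1.
#'
#' @param groups List of numeric vectors (each non-empty, total n >= 3).
#' @return List `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 1)) stopf("every group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3) stopf("need total n >= 3")
  k <- length(groups)
  g <- rep(seq_len(k), vapply(groups, length, 0L))
  r <- rank(x)
  rbar <- (n + 1) / 2
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_len(k), function(i) {
      length(r[g == i]) * (mean(r[g == i]) - rbar)^2
    }, 0))
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr <= 0) {
    # every value identical: no information, no group differences
    return(list(H = 0, p = 1, df = k - 1L, n = n))
  }
  h <- h / tie_corr
  list(H = h, p = stats::pchisq(h, df = k - 1, lower.tail = FALSE),
       df = k - 1L, n = n)
}

#' Eta-squared effect size for the Kruskal-Wallis test
#'
#' `eta^2 = (H - k + 1) / (n - k)`, floored at 0.
#'
#' @param H Kruskal-Wallis H statistic.
#' @param k Number of groups.
#' @param n Total sample size (> k).
#' @return Effect size in \[0, 1\].
#' @export
eta_squared <- function(H, k, n) {
  if (n <= k) stopf("need n > k")
  max(0, (H - k + 1) / (n - k))
}

#' Qualitative band for an eta-squared effect size
#'
#' Conventional cut points: < 0.01 negligible, 0.01-0.06 small, 0.06-0.14
#' medium, >= 0.14 large.
#'
#' @param eta2 Effect size in \[0, 1\].
#' @return Character label.
#' @export
interpret_eta_squared <- function(eta2) {
  if (is.na(eta2) || eta2 < 0) stopf("eta squared must be >= 0")
  if (eta2 < 0.01) return("negligible")
  if (eta2 < 0.06) return("small")
  if (eta2 < 0.14) return("medium")
  "large"
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise z statistics from mean ranks with tie correction; two-sided
#' p values multiplied by the number of pairs (capped at 1).
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return Data frame `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups) {
  k <- length(groups)
  if (k < 2) stopf("need >= 2 groups")
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 1)) stopf("every group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  g <- rep(seq_len(k), sizes)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- vapply(seq_len(k), function(i) mean(r[g == i]), 0)
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(c0) {
    i <- pairs[1, c0]
    j <- pairs[2, c0]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = i, group2 = j, z = z, p = p,
               p_adj = min(1, p * n_pairs))
  })
  do.call(rbind, rows)
}

#' Group-difference screen over interpretable features
#'
#' Runs the Kruskal-Wallis test (with eta-squared effect size) and Dunn's
#' Bonferroni-corrected post hoc test per feature, restricted to the
#' interpretable feature families, across the stage groups of a feature
#' table. No multiplicity correction is applied across features; the
#' Bonferroni correction applies within each feature's pairwise family.
#'
#' @param table Feature table (data.frame with `stage` plus feature
#'   columns).
#' @param families Regular expressions selecting interpretable features;
#'   defaults to morphology, echogenicity, histogram and GLCM families of
#'   both modalities.
#' @param alpha Significance level for the flags.
#' @return Data frame of class `group_stat_result`, one row per feature,
#'   sorted by p value: `feature`, `H`, `p`, `eta2`, `eta2_band`,
#'   `p_12`, `p_13`, `p_23` (Dunn-Bonferroni), `significant`,
#'   `sig_12`, `sig_13`, `sig_23`.
#' @export
feature_screen <- function(table,
                           families = c("^hfus\\.(morph|echo|hist|glcm)\\.",
                                        "^derm\\.[RGBHSV]\\.(hist|glcm)\\."),
                           alpha = 0.05) {
  stopifnot(is.data.frame(table), "stage" %in% colnames(table))
  stages <- sort(unique(table$stage))
  if (length(stages) < 2) stopf("need >= 2 stages present")
  cols <- setdiff(colnames(table), c("patient_id", "lesion_id", "stage"))
  if (length(families)) {
    cols <- cols[Reduce(`|`, lapply(families, grepl, x = cols))]
  }
  rows <- lapply(cols, function(cn) {
    v <- table[[cn]]
    ok <- !is.na(v)
    groups <- lapply(stages, function(s) v[ok & table$stage == s])
    if (any(vapply(groups, length, 0L) < 2)) return(NULL)
    kw <- kruskal_wallis(groups)
    e2 <- eta_squared(kw$H, length(groups), kw$n)
    dn <- dunn_posthoc(groups)
    pair_p <- function(a, b) {
      i <- which((stages[dn$group1] == a & stages[dn$group2] == b) |
                 (stages[dn$group1] == b & stages[dn$group2] == a))
      if (length(i)) dn$p_adj[i] else NA_real_
    }
    data.frame(feature = cn, H = kw$H, p = kw$p, eta2 = e2,
               eta2_band = interpret_eta_squared(e2),
               p_12 = pair_p(1, 2), p_13 = pair_p(1, 3), p_23 = pair_p(2, 3),
               significant = kw$p < alpha,
               sig_12 = !is.na(pair_p(1, 2)) & pair_p(1, 2) < alpha,
               sig_13 = !is.na(pair_p(1, 3)) & pair_p(1, 3) < alpha,
               sig_23 = !is.na(pair_p(2, 3)) & pair_p(2, 3) < alpha)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(0), H = numeric(0), p = numeric(0),
                      eta2 = numeric(0), eta2_band = character(0),
                      p_12 = numeric(0), p_13 = numeric(0), p_23 = numeric(0),
                      significant = logical(0), sig_12 = logical(0),
                      sig_13 = logical(0), sig_23 = logical(0))
  } else {
    out <- out[order(out$p), ]
    rownames(out) <- NULL
  }
  class(out) <- c("group_stat_result", "data.frame")
  out
}

#' Per-feature stage-group summary (medians and quartiles)
#'
#' Companion summary to [feature_screen()]: the per-stage median and
#' quartiles of each screened feature, the numbers a box-plot style figure
#' of stage trends would show.
#'
#' @param table Feature table.
#' @param features Feature names to summarize.
#' @return Data frame `feature`, `stage`, `n`, `q1`, `median`, `q3`.
#' @export
stage_group_summary <- function(table, features) {
  rows <- list()
  for (cn in features) {
    for (s in sort(unique(table$stage))) {
      v <- table[[cn]][table$stage == s]
      v <- v[!is.na(v)]
      if (!length(v)) next
      q <- q13(v)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = cn, stage = s, n = length(v), q1 = q[1], median = q[2],
        q3 = q[3])
    }
  }
  do.call(rbind, rows)
}
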