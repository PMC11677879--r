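test_that("Kruskal-Wallis matches the textbook rank formula", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)                      # no ties: closed form
  expect_equal(kw$df, 2L)
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), ">= 1 value")
})

test_that("Kruskal-Wallis and Dunn agree with independent references", {
  set.seed(14)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) {
      round(rnorm(sample(4:9, 1), mean = j / 2), 1)  # rounded: real ties
    })
    kw <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(groups)
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-9)

    # Dunn z against a direct evaluation of the mean-rank formula
    x <- unlist(groups)
    g <- rep(seq_len(k), vapply(groups, length, 0L))
    r <- rank(x)
    n <- length(x)
    ties <- table(x)
    tt <- sum(ties^3 - ties) / (12 * (n - 1))
    dn <- dunn_posthoc(groups)
    for (row in seq_len(nrow(dn))) {
      i1 <- dn$group1[row]
      i2 <- dn$group2[row]
      se <- sqrt((n * (n + 1) / 12 - tt) *
                 (1 / sum(g == i1) + 1 / sum(g == i2)))
      zref <- (mean(r[g == i1]) - mean(r[g == i2])) / se
      expect_equal(dn$z[row], zref, tolerance = 1e-9)
    }
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(3)
  groups <- lapply(1:3, function(j) runif(8, 0, j))
  h1 <- kruskal_wallis(groups)$H
  h2 <- kruskal_wallis(lapply(groups, function(v) exp(3 * v) - 1))$H
  h3 <- kruskal_wallis(lapply(groups, rank))$H  # not monotone jointly
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(h1, h3)))
})

test_that("eta squared follows its closed form with flooring", {
  expect_equal(eta_squared(7.2, 3, 9), (7.2 - 2) / 6)
  expect_equal(eta_squared(2, 3, 10), 0)       # H = k - 1 is the zero point
  expect_equal(eta_squared(1, 3, 10), 0)       # floored
  expect_error(eta_squared(5, 3, 3), "n > k")
  expect_identical(interpret_eta_squared(0.05), "small")
  expect_identical(interpret_eta_squared(0.09), "medium")
  expect_identical(interpret_eta_squared(0.2), "large")
  expect_identical(interpret_eta_squared(0.001), "negligible")
})

test_that("Dunn post hoc applies the Bonferroni cap", {
  same <- dunn_posthoc(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(same$p_adj == 1))
  set.seed(5)
  groups <- list(rnorm(10), rnorm(10, 0.5), rnorm(10, 4))
  dn <- dunn_posthoc(groups)
  expect_equal(nrow(dn), 3)
  expect_equal(dn$p_adj, pmin(1, dn$p * 3))
  expect_true(all(dn$p_adj >= dn$p))
  expect_error(dunn_posthoc(list(1:3)), ">= 2 groups")
})

test_that("well-separated extremes give the expected star pattern", {
  set.seed(8)
  g1 <- rnorm(30, 0, 1)
  g2 <- rnorm(30, 1.1, 1)     # overlaps both neighbours
  g3 <- rnorm(30, 2.2, 1)
  dn <- dunn_posthoc(list(g1, g2, g3))
  p13 <- dn$p_adj[dn$group1 == 1 & dn$group2 == 3]
  p23 <- dn$p_adj[dn$group1 == 2 & dn$group2 == 3]
  expect_lt(p13, 0.05)
  expect_gt(p23, p13)
})

test_that("the feature screen flags what differs and only that", {
  tab <- toy_feature_table(n_patients = 20L, per_patient = 3L, seed = 21)
  scr <- feature_screen(tab)
  expect_s3_class(scr, "group_stat_result")
  expect_true(all(diff(scr$p) >= 0))           # sorted by p
  informative <- c("hfus.morph.entry_echo.thickness_q3",
                   "hfus.hist.entry_echo.entropy")
  expect_true(all(scr$significant[scr$feature %in% informative]))
  # noise features are excluded from the default interpretable families
  # only via their family tag; here they are glcm-tagged, so they appear
  expect_true(all(c(informative,
                    sprintf("hfus.glcm.sleb.noise%d", 1:8)) %in% scr$feature))
  expect_identical(nrow(feature_screen(tab, families = "^none\\.")), 0L)
})

test_that("null features are rejected at close to the nominal rate", {
  set.seed(99)
  alpha <- 0.05
  rejections <- vapply(1:1000, function(i) {
    v <- rnorm(60)
    kruskal_wallis(split(v, rep(1:3, each = 20)))$p < alpha
  }, TRUE)
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("stage-group summaries report quartiles per stage", {
  tab <- toy_feature_table(seed = 2)
  s <- stage_group_summary(tab, "hfus.morph.entry_echo.thickness_q3")
  expect_equal(nrow(s), 3)
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  expect_true(all(diff(s$median) > 0))  # encoded stage trend
})
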