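test_that("z-score normalization uses training statistics only", {
  tr <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  te <- data.frame(a = c(2, 4), b = c(5, 9))
  zs <- suppressWarnings(zscore_fit_apply(tr, te))
  expect_equal(unname(zs$train[, "a"]), c(-1, 0, 1))   # sample sd
  expect_true(all(zs$train[, "b"] == 0))               # constant -> zeros
  expect_warning(zscore_fit_apply(tr), "constant")
  expect_equal(unname(zs$test[, "a"]), c(0, 2))        # train mean/sd applied
  expect_error(zscore_fit_apply(tr[1, , drop = FALSE]), ">= 2")
})

test_that("median imputation fills from the training fold and drops empties", {
  tr <- data.frame(a = c(1, 5, 9), b = c(NA, NA, NA), c = c(2, NA, 4))
  te <- data.frame(a = c(NA, 2), b = c(1, 2), c = c(NA, 0))
  im <- impute_missing(tr, te)
  expect_identical(im$dropped, "b")
  expect_equal(unname(im$train[, "c"]), c(2, 3, 4))
  expect_equal(unname(im$test[, "a"]), c(5, 2))
  expect_equal(unname(im$test[, "c"]), c(3, 0))
  # identity on complete data
  full <- data.frame(a = 1:4, b = 4:1)
  im2 <- impute_missing(full)
  expect_equal(unname(im2$train), unname(as.matrix(full)))
})

test_that("MRMR ranks a label-aligned feature first and duplicates late", {
  set.seed(1)
  n <- 60
  lab <- rep(1:3, each = 20)
  x <- data.frame(indicator = lab + rnorm(n, 0, 0.05))
  for (j in 1:6) x[[sprintf("noise%d", j)]] <- rnorm(n)
  r <- mrmr_rank(x, lab)
  expect_identical(r$feature[1], "indicator")

  # a near-duplicate of the winner is maximally redundant: its greedy score
  # collapses to relevance minus ~1 even though its relevance is near-perfect
  x$indicator_copy <- x$indicator + rnorm(n, 0, 1e-4)
  r2 <- mrmr_rank(x, lab)
  expect_true(r2$feature[1] %in% c("indicator", "indicator_copy"))
  other <- setdiff(c("indicator", "indicator_copy"), r2$feature[1])
  pos <- match(other, r2$feature)
  expect_gt(r2$relevance[pos], 0.9)
  expect_lt(r2$score[pos], r2$relevance[pos] - 0.9)

  r3 <- mrmr_rank(data.frame(a = lab + rnorm(n, 0, 0.1), b = rnorm(n)), lab)
  expect_equal(nrow(r3), 2)
  expect_error(mrmr_rank(x, rep(1, n)), "classes")
})

test_that("SMOTE balances counts with on-segment synthetic samples", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  lab <- c(rep(1, 24), rep(2, 10), rep(3, 6))
  sm <- smote_oversample(x, lab, seed = 4)
  expect_equal(as.integer(table(sm$labels)), c(24L, 24L, 24L))
  expect_equal(sm$x[seq_len(40), ], x)    # originals preserved
  # every synthetic class-3 row lies on a segment between two originals:
  # coordinate-wise within the class bounding box
  orig3 <- x[lab == 3, ]
  synth3 <- sm$x[sm$labels == 3, ][-seq_len(6), , drop = FALSE]
  for (j in 1:3) {
    expect_true(all(synth3[, j] >= min(orig3[, j]) - 1e-12))
    expect_true(all(synth3[, j] <= max(orig3[, j]) + 1e-12))
  }
  # already balanced: unchanged
  smb <- smote_oversample(x[1:30, ], rep(1:3, each = 10), seed = 1)
  expect_equal(nrow(smb$x), 30)
  expect_error(smote_oversample(x, c(rep(1, 39), 2)), "single member")
  sm1 <- smote_oversample(x, c(rep(1, 39), 2), duplicate_singletons = TRUE)
  expect_equal(as.integer(table(sm1$labels)), c(39L, 39L))
})

test_that("synthetic SMOTE samples interpolate a base point and a neighbour", {
  # 1-D makes the segment property exact and checkable
  x <- matrix(c(0, 1, 2, 3, 10, 20, 30), ncol = 1)
  lab <- c(1, 1, 1, 1, 2, 2, 2)
  sm <- smote_oversample(x, lab, k = 2, seed = 7)
  synth <- sm$x[sm$labels == 2, 1][-(1:3)]
  # neighbours of each class-2 point are within the class; k = 2 keeps
  # interpolations between adjacent values
  expect_true(all(synth >= 10 & synth <= 30))
})

test_that("leave-one-patient-out folds partition the lesions", {
  pats <- c("A", "A", "B", "C", "C", "C")
  f <- loo_patient_folds(pats)
  expect_equal(as.integer(table(f)), c(2L, 1L, 3L))
  expect_equal(length(unique(f)), 3)
  expect_identical(attr(f, "patients"), c("A", "B", "C"))
  expect_error(loo_patient_folds(rep("A", 4)), ">= 2")
})

test_that("confusion matrix and accuracy follow their definitions", {
  perfect <- confusion_and_accuracy(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))

  all1 <- confusion_and_accuracy(1:3, rep(1, 3))
  expect_equal(all1$accuracy, 1 / 3)
  expect_equal(sum(all1$confusion), 3)
  expect_error(confusion_and_accuracy(c(1, 4), c(1, 1)), "labels")
  expect_error(confusion_and_accuracy(1:3, 1:2), "length")
})

test_that("Cohen's kappa matches hand-computed anchors", {
  expect_equal(cohen_kappa(diag(c(10, 10, 10))), 1)
  expect_equal(cohen_kappa(matrix(5, 2, 2)), 0)
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2)), 0.4)
  # all mass in one diagonal cell: chance agreement 1 with perfect agreement
  expect_equal(cohen_kappa(matrix(c(4, 0, 0, 0), 2)), 1)
  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
  expect_equal(cohen_kappa(diag(3)) , 1)
})

test_that("kappa interpretation bands match the published rule", {
  expect_identical(interpret_kappa(0.73), "substantial")
  expect_identical(interpret_kappa(0.85), "almost perfect")
  expect_identical(interpret_kappa(-0.1), "no agreement")
  expect_identical(interpret_kappa(0.1), "none to slight")
  expect_identical(interpret_kappa(0.3), "fair")
  expect_identical(interpret_kappa(0.5), "moderate")
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("a label-leaking feature drives the classifier to the ceiling", {
  tab <- toy_feature_table(informative = FALSE, seed = 10)
  tab[["hfus.morph.entry_echo.leak"]] <- tab$stage
  rep_ <- select_and_classify(tab, "hfus_hand",
                              staging_grid(n_features = c(1L, 2L, 4L)),
                              seed = 1)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$kappa, 1)
})

test_that("staging is deterministic under a fixed seed", {
  tab <- toy_feature_table(n_patients = 10L, seed = 3)
  g <- staging_grid(n_features = c(2L, 4L), cost = c(1, 10),
                    gamma_mult = 1)
  r1 <- select_and_classify(tab, "hfus_hand", g, seed = 5)
  r2 <- select_and_classify(tab, "hfus_hand", g, seed = 5)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$per_fold, r2$per_fold)
})

test_that("feature combinations select the documented column families", {
  cols <- c("hfus.morph.entry_echo.thickness_q3", "derm.R.glcm.contrast",
            "derm.nn.f000")
  tab <- data.frame(patient_id = "P1", lesion_id = "L1", stage = 1,
                    check.names = FALSE)
  for (cn in cols) tab[[cn]] <- 1
  expect_identical(akstage:::feature_columns(tab, "hfus_hand"), cols[1])
  expect_identical(akstage:::feature_columns(tab, "derm_nn"), cols[3])
  expect_setequal(akstage:::feature_columns(tab, "hfus_derm_nn"),
                  cols[c(1, 3)])
  expect_setequal(akstage:::feature_columns(tab, "all"), cols)
  expect_error(feature_combination("nope"), "unknown")
})
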