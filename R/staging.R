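# Three-class AK staging from fused feature tables: z-score normalization,
# training-fold median imputation, MRMR feature ranking, SMOTE minority
# oversampling, SVM classification under patient-grouped leave-one-out
# validation, and agreement metrics (accuracy, unweighted Cohen's kappa).

#' Fit-and-apply z-score normalization
#'
#' Per-feature standardization using training statistics only (sample, n-1,
#' standard deviation); test data are transformed with the training mean and
#' sd. Constant training features map to all zeros with a warning.
#'
#' @param train,test Numeric data frames or matrices (same columns); `test`
#'   may be `NULL`.
#' @return List `train`, `test` (normalized matrices), `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stopf("z-score normalization needs >= 2 training rows")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  flat <- scl < 1e-12
  if (any(flat)) {
    warnf("%d constant feature(s) normalized to zero", sum(flat))
    scl[flat] <- 1
  }
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  tr[, flat] <- 0
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    te <- sweep(sweep(test, 2, ctr), 2, scl, "/")
    te[, flat] <- 0
  }
  list(train = tr, test = te, center = ctr, scale = scl)
}

#' Training-fold median imputation
#'
#' Fills missing values with the per-feature training median; features that
#' are missing in every training row are dropped from both tables.
#'
#' @param train,test Numeric data frames or matrices; `test` may be `NULL`.
#' @return List `train`, `test`, `dropped` (names of all-missing features).
#' @export
impute_missing <- function(train, test = NULL) {
  train <- as.matrix(train)
  med <- apply(train, 2, stats::median, na.rm = TRUE)
  dropped <- colnames(train)[is.na(med)]
  if (length(dropped)) {
    train <- train[, !colnames(train) %in% dropped, drop = FALSE]
    if (!is.null(test)) {
      test <- as.matrix(test)[, !colnames(test) %in% dropped, drop = FALSE]
    }
    med <- med[!names(med) %in% dropped]
  }
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      bad <- is.na(m[, j])
      if (any(bad)) m[bad, j] <- med[j]
    }
    m
  }
  train <- fill(train)
  if (!is.null(test)) test <- fill(as.matrix(test))
  list(train = train, test = test, dropped = dropped)
}

# One-way ANOVA relevance per feature column, on the eta-squared scale
# ssb / (ssb + ssw) in [0, 1]: a monotone transform of the F statistic that
# is commensurate with the [0, 1] correlation redundancy term of the MID
# difference criterion (raw F would drown the redundancy penalty).
anova_relevance <- function(x, g) {
  g <- as.factor(g)
  gm <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (lv in levels(g)) {
    sel <- g == lv
    m <- colMeans(x[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * (m - gm)^2
    ssw <- ssw + colSums(sweep(x[sel, , drop = FALSE], 2, m)^2)
  }
  tot <- ssb + ssw
  rel <- ssb / tot
  rel[tot < 1e-12] <- 0
  rel
}

#' MRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking with the difference
#' (MID) criterion: relevance is the one-way ANOVA association of a feature
#' with the class label on the eta-squared scale (a bounded, monotone
#' transform of the F statistic, so that the \[0, 1\] redundancy term can
#' compete); redundancy is the mean absolute Pearson correlation with the
#' already-selected features. The first feature maximizes relevance; each
#' next feature maximizes relevance minus redundancy. Zero-variance features
#' are excluded before ranking.
#'
#' @param features Numeric matrix or data frame (no missing values).
#' @param labels Class labels (>= 2 classes present).
#' @return Data frame `feature`, `score`, `relevance` in rank order.
#' @export
mrmr_rank <- function(features, labels) {
  x <- as.matrix(features)
  if (ncol(x) < 2) stopf("MRMR needs >= 2 features")
  if (length(unique(labels)) < 2) stopf("MRMR needs >= 2 classes")
  keep <- apply(x, 2, stats::sd) > 1e-12
  x <- x[, keep, drop = FALSE]
  p <- ncol(x)
  rel <- anova_relevance(x, labels)
  cm <- abs(suppressWarnings(stats::cor(x)))
  cm[!is.finite(cm)] <- 1
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  while (length(remaining) > 0) {
    sc <- if (length(selected) == 0) {
      rel[remaining]
    } else {
      rel[remaining] -
        rowMeans(cm[remaining, selected, drop = FALSE])
    }
    best <- remaining[which.max(sc)]
    scores <- c(scores, max(sc))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  data.frame(feature = colnames(x)[selected], score = scores,
             relevance = rel[selected], row.names = NULL)
}

#' SMOTE minority-class oversampling
#'
#' Upsamples every minority class to the majority count with synthetic
#' samples `x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`, where `x_nn` is one of
#' the `k` nearest same-class neighbours. Original rows are preserved.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param labels Class labels.
#' @param k Number of neighbours (reduced automatically to class size - 1).
#' @param seed Seed for the synthetic draws.
#' @param duplicate_singletons A class with a single member cannot be
#'   interpolated; with `TRUE` it is duplicated instead of erroring.
#' @return List `x` (matrix), `labels`; original rows first.
#' @export
smote_oversample <- function(x, labels, k = 5L, seed = 0L,
                             duplicate_singletons = FALSE) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  tab <- table(labels)
  target <- max(tab)
  out_x <- list(x)
  out_l <- list(labels)
  with_seed(seed, {
    for (cl in names(tab)) {
      need <- target - tab[[cl]]
      if (need == 0) next
      rows <- which(labels == cl)
      if (length(rows) == 1) {
        if (!duplicate_singletons) {
          stopf(paste0("class '%s' has a single member; SMOTE cannot ",
                       "interpolate - set duplicate_singletons = TRUE to ",
                       "fall back to duplication"), cl)
        }
        out_x[[length(out_x) + 1L]] <-
          x[rep(rows, need), , drop = FALSE]
        out_l[[length(out_l) + 1L]] <- rep(cl, need)
        next
      }
      xc <- x[rows, , drop = FALSE]
      kk <- min(k, nrow(xc) - 1L)
      d2 <- as.matrix(stats::dist(xc))^2
      diag(d2) <- Inf
      nn <- do.call(rbind, lapply(seq_len(nrow(xc)), function(i) {
        order(d2[i, ])[seq_len(kk)]
      }))
      base <- sample(nrow(xc), need, replace = TRUE)
      pick <- nn[cbind(base, sample(kk, need, replace = TRUE))]
      u <- stats::runif(need)
      synth <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      out_x[[length(out_x) + 1L]] <- synth
      out_l[[length(out_l) + 1L]] <- rep(cl, need)
    }
  })
  lab_out <- unlist(out_l, use.names = FALSE)
  if (is.numeric(labels)) lab_out <- as.numeric(lab_out)
  list(x = do.call(rbind, out_x), labels = lab_out)
}

#' Patient-grouped leave-one-out fold assignment
#'
#' One fold per patient; fold i's test set is all lesions of patient i.
#'
#' @param patients Character vector of per-lesion patient ids (>= 2 distinct
#'   patients).
#' @return Integer fold id per lesion; attribute `"patients"` maps fold ->
#'   patient.
#' @export
loo_patient_folds <- function(patients) {
  up <- unique(patients)
  if (length(up) < 2) stopf("leave-one-out needs >= 2 patients")
  out <- match(patients, up)
  attr(out, "patients") <- up
  out
}

#' Confusion matrix and accuracy for three-class staging
#'
#' @param true,pred Integer labels in \{1, 2, 3\} of equal length.
#' @return List `confusion` (3 x 3 matrix, rows = true) and `accuracy`.
#' @export
confusion_and_accuracy <- function(true, pred) {
  if (length(true) != length(pred)) stopf("label vectors differ in length")
  if (!all(c(true, pred) %in% 1:3)) stopf("labels must be in {1, 2, 3}")
  cm <- table(factor(true, levels = 1:3), factor(pred, levels = 1:3))
  cm <- matrix(as.numeric(cm), 3, 3,
               dimnames = list(true = 1:3, pred = 1:3))
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

#' Unweighted Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (trace /
#' n) and chance agreement `p_e` (sum of row-total x column-total products /
#' n^2). When `p_e` = 1 the statistic is defined as 1 for perfect observed
#' agreement and 0 otherwise (with a warning).
#'
#' @param m Square count matrix (rows = true, columns = predicted).
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(m) {
  m <- as.matrix(m)
  n <- sum(m)
  if (n <= 0) stopf("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    warnf("chance agreement is 1; kappa undefined, returning 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Qualitative agreement band for a kappa value
#'
#' Standard interpretation: below 0 no agreement, 0-0.20 none to slight,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00
#' almost perfect.
#'
#' @param value Kappa in \[-1, 1\].
#' @return Character label.
#' @export
interpret_kappa <- function(value) {
  if (is.na(value) || value < -1 || value > 1) {
    stopf("kappa must be in [-1, 1]")
  }
  if (value < 0) return("no agreement")
  if (value <= 0.20) return("none to slight")
  if (value <= 0.40) return("fair")
  if (value <= 0.60) return("moderate")
  if (value <= 0.80) return("substantial")
  "almost perfect"
}

# --- feature-set combinations ----------------------------------------------

#' Feature-set combination definitions
#'
#' Named regular-expression bundles selecting feature columns by modality
#' and family, mirroring the feature-set comparisons of multimodal AK
#' staging: HFUS handcrafted, dermatoscopy handcrafted, dermatoscopy CNN,
#' and their combinations.
#'
#' @param name One of `"hfus_hand"`, `"derm_hand"`, `"derm_nn"`,
#'   `"hfus_derm_hand"`, `"derm_hand_nn"`, `"hfus_derm_nn"`, `"all"`.
#' @return Character vector of regular expressions matched against feature
#'   names.
#' @export
feature_combination <- function(name) {
  switch(name,
    hfus_hand = "^hfus\\.",
    derm_hand = "^derm\\.[RGBHSV]\\.",
    derm_nn = "^derm\\.nn\\.",
    hfus_derm_hand = c("^hfus\\.", "^derm\\.[RGBHSV]\\."),
    derm_hand_nn = c("^derm\\.[RGBHSV]\\.", "^derm\\.nn\\."),
    hfus_derm_nn = c("^hfus\\.", "^derm\\.nn\\."),
    all = c("^hfus\\.", "^derm\\."),
    stopf("unknown feature combination '%s'", name)
  )
}

#' Hyperparameter grid for the staging classifier
#'
#' Candidate feature-count cutoffs on the MRMR ranking, SVM cost values,
#' gamma multipliers of the 1/p heuristic, and the number of patient-grouped
#' inner cross-validation folds used to pick among them.
#'
#' @param n_features Candidate numbers of top-ranked features.
#' @param cost SVM cost grid.
#' @param gamma_mult Multipliers of the 1/p RBF gamma heuristic.
#' @param inner_folds Inner patient-grouped CV folds.
#' @return List consumed by [select_and_classify()].
#' @export
staging_grid <- function(n_features = c(5L, 10L, 15L, 20L, 30L, 40L),
                         cost = c(0.1, 1, 10, 100),
                         gamma_mult = c(0.1, 1, 10), inner_folds = 5L) {
  list(n_features = n_features, cost = cost, gamma_mult = gamma_mult,
       inner_folds = inner_folds)
}

feature_columns <- function(table, combination) {
  pats <- if (length(combination) == 1 && combination %in%
              c("hfus_hand", "derm_hand", "derm_nn", "hfus_derm_hand",
                "derm_hand_nn", "hfus_derm_nn", "all")) {
    feature_combination(combination)
  } else {
    combination
  }
  cols <- setdiff(colnames(table), c("patient_id", "lesion_id", "stage"))
  cols[Reduce(`|`, lapply(pats, grepl, x = cols))]
}

fit_svm <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = factor(y, levels = 1:3), kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

#' Feature selection and SVM staging under patient-grouped leave-one-out
#'
#' The full staging procedure for one feature-set combination. Outer loop:
#' leave-one-patient-out. Within each training fold: median imputation,
#' z-score normalization, MRMR ranking, then a joint grid search over the
#' feature-count cutoff and the SVM cost/gamma on patient-grouped inner
#' cross-validation; the winning configuration is refit on the SMOTE-
#' balanced training fold and applied to the held-out patient. All
#' statistics (imputation medians, normalization, ranking, hyperparameters,
#' SMOTE) are computed from training rows only.
#'
#' @param table Feature table: data.frame with `patient_id`, `lesion_id`,
#'   `stage` plus feature columns.
#' @param combination Combination name (see [feature_combination()]) or a
#'   character vector of regular expressions.
#' @param grid Hyperparameter grid (see `staging_grid()`): candidate feature
#'   counts, SVM cost values, gamma multipliers of the 1/p heuristic, and
#'   the number of inner folds.
#' @param seed Master seed (inner folds, SMOTE).
#' @param duplicate_singletons Passed to [smote_oversample()].
#' @return Object of class `staging_report`: confusion matrix, accuracy,
#'   unweighted Cohen's kappa (+ interpretation), modal selected feature
#'   count, per-fold selections and per-lesion predictions.
#' @export
select_and_classify <- function(table, combination = "hfus_hand",
                                grid = staging_grid(), seed = 0L,
                                duplicate_singletons = FALSE) {
  cols <- feature_columns(table, combination)
  if (length(cols) < 2) stopf("combination selects fewer than 2 features")
  stages <- table$stage
  if (!all(stages %in% 1:3)) stopf("stage labels must be in {1, 2, 3}")
  folds <- loo_patient_folds(table$patient_id)
  n_folds <- length(attr(folds, "patients"))
  seeds <- derive_seeds(seed, n_folds)

  pred_all <- rep(NA_integer_, nrow(table))
  fold_rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    imp <- impute_missing(table[tr, cols, drop = FALSE],
                          table[te, cols, drop = FALSE])
    zs <- suppressWarnings(zscore_fit_apply(imp$train, imp$test))
    ytr <- stages[tr]
    rank <- mrmr_rank(zs$train, ytr)
    nf_grid <- unique(pmin(grid$n_features, nrow(rank)))
    inner <- patient_folds(table$patient_id[tr],
                           min(grid$inner_folds,
                               length(unique(table$patient_id[tr]))),
                           seed = seeds[f])
    inner_id <- inner[table$patient_id[tr]]

    best <- NULL
    for (nf in sort(nf_grid)) {
      feats <- rank$feature[seq_len(nf)]
      xsub <- zs$train[, feats, drop = FALSE]
      for (g in seq_len(max(inner_id))) {
        it <- which(inner_id != g)
        iv <- which(inner_id == g)
        if (length(unique(ytr[it])) < length(unique(ytr))) next
        sm <- tryCatch(
          smote_oversample(xsub[it, , drop = FALSE], ytr[it], seed = seeds[f],
                           duplicate_singletons = duplicate_singletons),
          error = function(e) NULL)
        if (is.null(sm)) next
        for (cost in grid$cost) {
          for (gm in grid$gamma_mult) {
            gamma <- gm / nf
            mdl <- fit_svm(sm$x, sm$labels, cost, gamma)
            acc <- mean(as.integer(as.character(
              stats::predict(mdl, xsub[iv, , drop = FALSE]))) == ytr[iv])
            key <- sprintf("%d|%g|%g", nf, cost, gm)
            if (is.null(best$scores[[key]])) best$scores[[key]] <- c()
            best$scores[[key]] <- c(best$scores[[key]], acc)
          }
        }
      }
    }
    if (is.null(best$scores) || length(best$scores) == 0) {
      # every inner split lost a class (tiny cohort): fall back to the most
      # regularized default rather than aborting the outer loop
      warnf(paste0("fold %d: all inner validation splits were degenerate ",
                   "(a class absent); falling back to the default ",
                   "configuration"), f)
      pick <- data.frame(nf = min(nf_grid), cost = grid$cost[1],
                         gm = grid$gamma_mult[1], score = NA_real_)
    } else {
      means <- vapply(best$scores, mean, 0)
      keys <- do.call(rbind, strsplit(names(means), "|", fixed = TRUE))
      cfg <- data.frame(nf = as.integer(keys[, 1]),
                        cost = as.numeric(keys[, 2]),
                        gm = as.numeric(keys[, 3]), score = means)
      # tie-break: best score, then fewest features, then smallest cost/gamma
      cfg <- cfg[order(-cfg$score, cfg$nf, cfg$cost, cfg$gm), ]
      pick <- cfg[1, ]
    }

    feats <- rank$feature[seq_len(pick$nf)]
    sm <- smote_oversample(zs$train[, feats, drop = FALSE], ytr,
                           seed = seeds[f],
                           duplicate_singletons = duplicate_singletons)
    mdl <- fit_svm(sm$x, sm$labels, pick$cost, pick$gm / pick$nf)
    pred_all[te] <- as.integer(as.character(
      stats::predict(mdl, zs$test[, feats, drop = FALSE])))
    fold_rows[[f]] <- data.frame(
      fold = f, patient_id = attr(folds, "patients")[f],
      n_selected = pick$nf, cost = pick$cost, gamma_mult = pick$gm,
      inner_score = pick$score)
  }

  ca <- confusion_and_accuracy(stages, pred_all)
  kap <- cohen_kappa(ca$confusion)
  per_fold <- do.call(rbind, fold_rows)
  counts <- table(per_fold$n_selected)
  modal_nf <- as.integer(names(counts)[which.max(counts)])
  structure(list(
    combination = paste(combination, collapse = ","),
    confusion = ca$confusion, accuracy = ca$accuracy, kappa = kap,
    kappa_band = interpret_kappa(kap), n_features = modal_nf,
    per_fold = per_fold,
    predictions = data.frame(patient_id = table$patient_id,
                             lesion_id = table$lesion_id, stage = stages,
                             predicted = pred_all)),
    class = "staging_report")
}

#' @export
print.staging_report <- function(x, ...) {
  cat(sprintf(paste0("<staging_report [%s]: accuracy %.4f, kappa %.4f ",
                     "(%s), %d features>\n"),
              x$combination, x$accuracy, x$kappa, x$kappa_band, x$n_features))
  print(x$confusion)
  invisible(x)
}
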