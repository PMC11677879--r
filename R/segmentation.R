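#' Crop an HFUS scan laterally
#'
#' Clinical skin B-scans are wider than the region of interest; analysis
#' uses a fixed-width lateral window (512 px for the 1024 px clinical
#' format).
#'
#' @param scan An [hfus_scan()].
#' @param target_width Desired width in px (<= scan width).
#' @param center Either `"middle"` (default) or a lateral column index at
#'   which to center the window; the window is clamped to the image bounds.
#' @return The cropped [hfus_scan()]; depth is unchanged.
#' @export
crop_scan <- function(scan, target_width, center = "middle") {
  stopifnot(inherits(scan, "hfus_scan"))
  w <- ncol(scan$pixels)
  if (target_width > w) {
    stopf("target width %d exceeds scan width %d", target_width, w)
  }
  start <- if (identical(center, "middle")) {
    (w - target_width) %/% 2L + 1L
  } else {
    min(max(as.integer(center) - target_width %/% 2L, 1L),
        w - target_width + 1L)
  }
  out <- scan
  out$pixels <- scan$pixels[, start:(start + target_width - 1L), drop = FALSE]
  out
}

#' Dice overlap index
#'
#' `2|A  B| / (|A| + |B|)` between two binary masks of one shape. Two empty
#' masks agree on absence and score 1.
#'
#' @param pred,ref Logical (or 0/1) matrices of identical shape.
#' @return A value in \[0, 1\].
#' @export
dice_index <- function(pred, ref) {
  pred <- as.matrix(pred) > 0
  ref <- as.matrix(ref) > 0
  if (!identical(dim(pred), dim(ref))) stopf("mask shapes differ")
  denom <- sum(pred) + sum(ref)
  if (denom == 0) return(1)
  2 * sum(pred & ref) / denom
}

#' Segmentation model configuration
#'
#' Hyperparameters of the compact contextual-feature-pyramid encoder-decoder
#' used for skin-layer segmentation. The network downsamples twice (factor
#' 4); each encoder stage carries a pyramid block of parallel 3x3
#' convolutions at the configured dilation rates whose outputs are
#' concatenated and fused, and the decoder restores full resolution through
#' skip connections.
#'
#' @param input_height,input_width Expected scan size; must be divisible
#'   by 4.
#' @param widths Channel widths of the three encoder stages.
#' @param dilations Dilation rates of the pyramid branches.
#' @param n_classes 3 (background, entry echo, SLEB) or 4 (adds a predicted
#'   dermis-reference class).
#' @param epochs,lr Training schedule (Adam).
#' @param seed Seed for weight initialization and batch shuffling.
#' @return An object of class `seg_model_config`.
#' @export
seg_model_config <- function(input_height = 128L, input_width = 256L,
                             widths = c(6L, 12L, 24L), dilations = c(1L, 2L, 4L),
                             n_classes = 3L, epochs = 20L, lr = 3e-3,
                             seed = 0L) {
  if (!n_classes %in% c(3L, 4L)) stopf("n_classes must be 3 or 4")
  if (length(widths) != 3 || any(widths < 2)) {
    stopf("widths must be three channel counts >= 2")
  }
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 widths = as.integer(widths),
                 dilations = as.integer(dilations),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "seg_model_config")
}

#' Build a segmentation model
#'
#' Instantiates the encoder-decoder with seeded He-normal weights. The
#' parameter count is reported via `message()`.
#'
#' @param config A [seg_model_config()].
#' @return An object of class `seg_model` holding `config` and `params`.
#' @export
build_model <- function(config = seg_model_config()) {
  stopifnot(inherits(config, "seg_model_config"))
  if (config$input_height %% 4L != 0L || config$input_width %% 4L != 0L) {
    stopf("input size %d x %d is not divisible by the downsampling factor 4",
          config$input_height, config$input_width)
  }
  w <- config$widths
  nb <- length(config$dilations)
  params <- with_seed(config$seed, {
    p <- list(
      stem = new_conv(1L, w[1], 3L),
      down1 = new_conv(w[1], w[2], 3L),
      down2 = new_conv(w[2], w[3], 3L),
      cfp1_fuse = new_conv(nb * (w[2] %/% 2L), w[2], 1L),
      cfp2_fuse = new_conv(nb * (w[3] %/% 2L), w[3], 1L),
      up1 = new_conv(w[3], w[2], 1L),
      up2 = new_conv(w[2], w[1], 1L),
      head = new_conv(w[1], config$n_classes, 1L)
    )
    for (i in seq_len(nb)) {
      p[[sprintf("cfp1_b%d", i)]] <- new_conv(w[2], w[2] %/% 2L, 3L)
      p[[sprintf("cfp2_b%d", i)]] <- new_conv(w[3], w[3] %/% 2L, 3L)
    }
    p
  })
  model <- structure(list(config = config, params = params),
                     class = "seg_model")
  message(sprintf("segmentation model built: %d trainable parameters",
                  n_params(params)))
  model
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model: %d x %d input, widths %s, %d classes, %d params>\n",
              x$config$input_height, x$config$input_width,
              paste(x$config$widths, collapse = "/"), x$config$n_classes,
              n_params(x$params)))
  invisible(x)
}

# Forward pass; with want_cache the per-layer patch matrices are kept so the
# backward pass can reuse them.
seg_forward <- function(pp, x, dils, want_cache = TRUE) {
  nb <- length(dils)
  if (!want_cache) {
    a0 <- relu_f(conv_f(x, pp$stem))
    a1 <- relu_f(conv_f(a0, pp$down1, stride = 2L))
    b1 <- lapply(seq_len(nb), function(i)
      relu_f(conv_f(a1, pp[[sprintf("cfp1_b%d", i)]], dil = dils[i])))
    f1 <- relu_f(conv_f(do.call(cbind3, b1), pp$cfp1_fuse) + a1)
    a2 <- relu_f(conv_f(f1, pp$down2, stride = 2L))
    b2 <- lapply(seq_len(nb), function(i)
      relu_f(conv_f(a2, pp[[sprintf("cfp2_b%d", i)]], dil = dils[i])))
    f2 <- relu_f(conv_f(do.call(cbind3, b2), pp$cfp2_fuse) + a2)
    r1 <- relu_f(conv_f(upsample2_f(f2), pp$up1) + f1)
    r2 <- relu_f(conv_f(upsample2_f(r1), pp$up2) + a0)
    return(list(logits = conv_f(r2, pp$head)))
  }
  cols <- list()
  ft <- conv_ft(x, pp$stem)
  cols$stem <- ft$cols
  a0 <- relu_f(ft$y)
  ft <- conv_ft(a0, pp$down1, stride = 2L)
  cols$down1 <- ft$cols
  a1 <- relu_f(ft$y)
  b1 <- vector("list", nb)
  for (i in seq_len(nb)) {
    ft <- conv_ft(a1, pp[[sprintf("cfp1_b%d", i)]], dil = dils[i])
    cols[[sprintf("cfp1_b%d", i)]] <- ft$cols
    b1[[i]] <- relu_f(ft$y)
  }
  cc1 <- do.call(cbind3, b1)
  ft <- conv_ft(cc1, pp$cfp1_fuse)
  cols$cfp1_fuse <- ft$cols
  f1 <- relu_f(ft$y + a1)
  ft <- conv_ft(f1, pp$down2, stride = 2L)
  cols$down2 <- ft$cols
  a2 <- relu_f(ft$y)
  b2 <- vector("list", nb)
  for (i in seq_len(nb)) {
    ft <- conv_ft(a2, pp[[sprintf("cfp2_b%d", i)]], dil = dils[i])
    cols[[sprintf("cfp2_b%d", i)]] <- ft$cols
    b2[[i]] <- relu_f(ft$y)
  }
  cc2 <- do.call(cbind3, b2)
  ft <- conv_ft(cc2, pp$cfp2_fuse)
  cols$cfp2_fuse <- ft$cols
  f2 <- relu_f(ft$y + a2)
  u1in <- upsample2_f(f2)
  ft <- conv_ft(u1in, pp$up1)
  cols$up1 <- ft$cols
  r1 <- relu_f(ft$y + f1)
  u2in <- upsample2_f(r1)
  ft <- conv_ft(u2in, pp$up2)
  cols$up2 <- ft$cols
  r2 <- relu_f(ft$y + a0)
  ft <- conv_ft(r2, pp$head)
  cols$head <- ft$cols
  list(logits = ft$y,
       cache = list(x = x, a0 = a0, a1 = a1, b1 = b1, cc1 = cc1, f1 = f1,
                    a2 = a2, b2 = b2, cc2 = cc2, f2 = f2, u1in = u1in,
                    r1 = r1, u2in = u2in, r2 = r2, cols = cols))
}

seg_backward <- function(pp, cache, dlogits, dils) {
  nb <- length(dils)
  g <- list()
  ch <- cache
  cls <- cache$cols

  bh <- conv_b(cls$head, pp$head, dlogits, dim(ch$r2))
  g$head <- bh
  dr2 <- relu_b(ch$r2, bh$dx)
  bu2 <- conv_b(cls$up2, pp$up2, dr2, dim(ch$u2in))
  g$up2 <- bu2
  da0 <- dr2                      # residual branch
  dr1 <- upsample2_b(bu2$dx)
  dr1 <- relu_b(ch$r1, dr1)
  bu1 <- conv_b(cls$up1, pp$up1, dr1, dim(ch$u1in))
  g$up1 <- bu1
  df1 <- dr1                      # residual branch
  df2 <- upsample2_b(bu1$dx)

  # second pyramid block
  dz2 <- relu_b(ch$f2, df2)
  bf2 <- conv_b(cls$cfp2_fuse, pp$cfp2_fuse, dz2, dim(ch$cc2))
  g$cfp2_fuse <- bf2
  da2 <- dz2                      # residual
  half <- dim(ch$b2[[1]])[3]
  for (i in seq_len(nb)) {
    sl <- ((i - 1L) * half + 1L):(i * half)
    dbi <- relu_b(ch$b2[[i]], bf2$dx[, , sl, drop = FALSE])
    nm <- sprintf("cfp2_b%d", i)
    bb <- conv_b(cls[[nm]], pp[[nm]], dbi, dim(ch$a2), dil = dils[i])
    g[[nm]] <- bb
    da2 <- da2 + bb$dx
  }
  da2 <- relu_b(ch$a2, da2)
  bd2 <- conv_b(cls$down2, pp$down2, da2, dim(ch$f1), stride = 2L)
  g$down2 <- bd2
  df1 <- df1 + bd2$dx

  # first pyramid block
  dz1 <- relu_b(ch$f1, df1)
  bf1 <- conv_b(cls$cfp1_fuse, pp$cfp1_fuse, dz1, dim(ch$cc1))
  g$cfp1_fuse <- bf1
  da1 <- dz1
  half <- dim(ch$b1[[1]])[3]
  for (i in seq_len(nb)) {
    sl <- ((i - 1L) * half + 1L):(i * half)
    dbi <- relu_b(ch$b1[[i]], bf1$dx[, , sl, drop = FALSE])
    nm <- sprintf("cfp1_b%d", i)
    bb <- conv_b(cls[[nm]], pp[[nm]], dbi, dim(ch$a1), dil = dils[i])
    g[[nm]] <- bb
    da1 <- da1 + bb$dx
  }
  da1 <- relu_b(ch$a1, da1)
  bd1 <- conv_b(cls$down1, pp$down1, da1, dim(ch$a0), stride = 2L)
  g$down1 <- bd1
  da0 <- da0 + bd1$dx
  da0 <- relu_b(ch$a0, da0)
  g$stem <- conv_b(cls$stem, pp$stem, da0, dim(ch$x))
  g
}

scan_to_input <- function(scan) {
  px <- if (inherits(scan, "hfus_scan")) scan$pixels else scan
  array(px / 255 - 0.5, dim = c(nrow(px), ncol(px), 1L))
}

masks_to_labels <- function(masks, n_classes = 3L) {
  lab <- matrix(0L, nrow(masks$entry_echo), ncol(masks$entry_echo))
  lab[masks$entry_echo] <- 1L
  lab[masks$sleb] <- 2L
  if (n_classes == 4L) lab[masks$dermis_reference] <- 3L
  lab
}

# Train on a list of (input array, label matrix) pairs; returns params.
seg_fit <- function(model, xs, ys, epochs = NULL, lr = NULL, seed = NULL,
                    verbose = FALSE) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  seed <- seed %||% cfg$seed
  pp <- model$params
  st <- adam_new(pp)
  orders <- with_seed(seed, {
    lapply(seq_len(epochs), function(e) sample(length(xs)))
  })
  for (e in seq_len(epochs)) {
    tot <- 0
    for (i in orders[[e]]) {
      fw <- seg_forward(pp, xs[[i]], cfg$dilations)
      ls <- seg_loss(fw$logits, ys[[i]])
      tot <- tot + ls$loss
      gr <- seg_backward(pp, fw$cache, ls$dlogits, cfg$dilations)
      up <- adam_step(pp, gr, st, lr = lr)
      pp <- up$params
      st <- up$state
    }
    if (verbose) message(sprintf("epoch %d/%d: mean loss %.4f", e, epochs,
                                 tot / length(xs)))
  }
  model$params <- pp
  model
}

# Patient-grouped fold assignment: returns integer fold id per patient.
patient_folds <- function(patients, n_folds, seed = 0L) {
  up <- unique(patients)
  if (length(up) < n_folds) {
    stopf("cannot split %d patient(s) into %d patient-grouped folds",
          length(up), n_folds)
  }
  shuffled <- with_seed(seed, sample(up))
  fold_of <- rep(seq_len(n_folds), length.out = length(up))
  stats::setNames(fold_of[match(up, shuffled)], up)
}

#' Train the layer-segmentation network with patient-grouped cross-validation
#'
#' Splits the cohort's patients into `n_folds` folds, trains one model per
#' fold on its training split only, and scores the held-out lesions with the
#' per-layer Dice index.
#'
#' @param cohort An `ak_cohort` with HFUS scans and ground-truth masks.
#' @param n_folds Number of folds (>= 2, <= number of patients).
#' @param config A [seg_model_config()] matching the cohort's scan size.
#' @param verbose Print per-epoch losses?
#' @return A list of class `seg_cv_result`: `models` (one per fold),
#'   `report` (data.frame: fold, layer, lesion-level Dice), `summary`
#'   (mean Dice per layer) and `fold_of` (named patient -> fold map).
#' @export
train_segmentation <- function(cohort, n_folds = 10L,
                               config = seg_model_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "ak_cohort"))
  pats <- cohort_patients(cohort)
  fold_of <- patient_folds(pats, n_folds, seed = config$seed)
  lesion_fold <- fold_of[pats]
  seeds <- derive_seeds(config$seed, n_folds)
  xs <- lapply(cohort$lesions, function(l) scan_to_input(l$hfus$scan))
  ys <- lapply(cohort$lesions, function(l)
    masks_to_labels(l$hfus$masks, config$n_classes))

  models <- vector("list", n_folds)
  rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(lesion_fold != f)
    te <- which(lesion_fold == f)
    if (length(intersect(pats[tr], pats[te])) > 0) {
      stop("internal error: patient present in both train and validation")
    }
    model <- suppressMessages(build_model(config))
    model <- seg_fit(model, xs[tr], ys[tr], seed = seeds[f],
                     verbose = verbose)
    models[[f]] <- model
    for (i in te) {
      pred <- segment_layers(model, cohort$lesions[[i]]$hfus$scan,
                             quiet = TRUE)
      gt <- cohort$lesions[[i]]$hfus$masks
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, lesion_id = cohort$lesions[[i]]$lesion_id,
        dice_entry = dice_index(pred$entry_echo, gt$entry_echo),
        dice_sleb = dice_index(pred$sleb, gt$sleb))
    }
  }
  report <- do.call(rbind, rows)
  structure(list(
    models = models, report = report,
    summary = c(dice_entry = mean(report$dice_entry),
                dice_sleb = mean(report$dice_sleb)),
    fold_of = fold_of), class = "seg_cv_result")
}

#' @export
print.seg_cv_result <- function(x, ...) {
  cat(sprintf("<seg_cv_result: %d folds, mean Dice entry echo %.3f, SLEB %.3f>\n",
              length(x$models), x$summary["dice_entry"],
              x$summary["dice_sleb"]))
  invisible(x)
}

keep_largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# Dermis reference: the band of `depth` px directly below the lower SLEB
# boundary (or below the entry echo where SLEB is absent), per column.
derive_dermis_reference <- function(entry, sleb, depth = 50L) {
  h <- nrow(entry)
  ref <- matrix(FALSE, h, ncol(entry))
  for (j in seq_len(ncol(entry))) {
    col_any <- entry[, j] | sleb[, j]
    if (!any(col_any)) next
    bottom <- max(which(col_any))
    if (bottom >= h) next
    ref[(bottom + 1L):min(h, bottom + depth), j] <- TRUE
  }
  ref
}

#' Save / load a segmentation model checkpoint
#'
#' Checkpoints are RDS files holding the model's configuration and weights.
#'
#' @param model A `seg_model`.
#' @param path Checkpoint path.
#' @return `load_seg_model` returns the model; `save_seg_model` the path,
#'   invisibly.
#' @export
save_seg_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  obj <- readRDS(path)
  if (!all(c("config", "params") %in% names(obj))) {
    stopf("'%s' is not a segmentation checkpoint", path)
  }
  structure(obj, class = "seg_model")
}

#' Segment skin layers in one scan
#'
#' Runs the trained network, takes the per-pixel argmax, keeps the largest
#' connected component per layer and derives the dermis-reference band when
#' it is not a predicted class. An empty entry-echo prediction is flagged as
#' degenerate (attribute `degenerate`, plus a warning) rather than silently
#' returned.
#'
#' @param model A trained [build_model()] / [train_segmentation()] model.
#' @param scan An [hfus_scan()] sized compatibly with the model.
#' @param dermis_depth Depth in px of the derived dermis-reference band.
#' @param quiet Suppress the degenerate-result warning?
#' @return A [layer_mask_set()]; attribute `degenerate` is `TRUE` when the
#'   entry echo came back empty.
#' @export
segment_layers <- function(model, scan, dermis_depth = 50L, quiet = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  x <- scan_to_input(scan)
  if (dim(x)[1] %% 4L != 0L || dim(x)[2] %% 4L != 0L) {
    stopf("scan size %d x %d incompatible with the factor-4 downsampling",
          dim(x)[1], dim(x)[2])
  }
  fw <- seg_forward(model$params, x, model$config$dilations,
                    want_cache = FALSE)
  cls <- argmax3(fw$logits) - 1L
  entry <- keep_largest_component(cls == 1L)
  sleb <- keep_largest_component(cls == 2L & !entry)
  dref <- if (model$config$n_classes == 4L) {
    keep_largest_component(cls == 3L & !entry & !sleb)
  } else {
    derive_dermis_reference(entry, sleb, dermis_depth)
  }
  out <- layer_mask_set(entry, sleb, dref)
  degenerate <- !any(entry)
  if (degenerate && !quiet) {
    warnf("degenerate segmentation: empty entry-echo prediction")
  }
  attr(out, "degenerate") <- degenerate
  out
}
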