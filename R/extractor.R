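# Pluggable CNN feature extractors for dermatoscopy images. The interface
# mirrors the common transfer-learning pattern: a network trained to
# discriminate AK from non-AK images supplies its last fully connected
# layer's activations as features for downstream staging.

# --- compact classification network -----------------------------------------

cls_init <- function(seed = 0L, cin = 3L, widths = c(8L, 16L), fdim = 16L,
                     n_classes = 2L) {
  with_seed(seed, {
    list(
      c1 = new_conv(cin, widths[1], 3L),
      c2 = new_conv(widths[1], widths[2], 3L),
      fc = list(W = matrix(stats::rnorm(fdim * widths[2],
                                        sd = sqrt(2 / widths[2])), fdim),
                b = rep(0, fdim), k = 0L),
      out = list(W = matrix(stats::rnorm(n_classes * fdim,
                                         sd = sqrt(2 / fdim)), n_classes),
                 b = rep(0, n_classes), k = 0L)
    )
  })
}

cls_forward <- function(pp, x, want_cache = FALSE) {
  if (want_cache) {
    ft1 <- conv_ft(x, pp$c1, stride = 2L)
    a1 <- relu_f(ft1$y)
    ft2 <- conv_ft(a1, pp$c2, stride = 2L)
    a2 <- relu_f(ft2$y)
  } else {
    a1 <- relu_f(conv_f(x, pp$c1, stride = 2L))
    a2 <- relu_f(conv_f(a1, pp$c2, stride = 2L))
  }
  d <- dim(a2)
  g <- colMeans(matrix(a2, d[1] * d[2], d[3]))   # global average pool
  f <- relu_f(as.numeric(pp$fc$W %*% g + pp$fc$b))
  logits <- as.numeric(pp$out$W %*% f + pp$out$b)
  res <- list(logits = logits, features = f)
  if (want_cache) {
    res$cache <- list(x = x, a1 = a1, a2 = a2, g = g, f = f,
                      cols1 = ft1$cols, cols2 = ft2$cols)
  }
  res
}

cls_backward <- function(pp, cache, dlogits) {
  g <- list()
  g$out <- list(dW = outer(dlogits, cache$f), db = dlogits)
  df <- as.numeric(t(pp$out$W) %*% dlogits)
  df <- df * (cache$f > 0)
  g$fc <- list(dW = outer(df, cache$g), db = df)
  dg <- as.numeric(t(pp$fc$W) %*% df)
  d <- dim(cache$a2)
  da2 <- array(rep(dg, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  da2 <- relu_b(cache$a2, da2)
  b2 <- conv_b(cache$cols2, pp$c2, da2, dim(cache$a1), stride = 2L)
  g$c2 <- b2
  da1 <- relu_b(cache$a1, b2$dx)
  g$c1 <- conv_b(cache$cols1, pp$c1, da1, dim(cache$x), stride = 2L)
  g
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

derm_to_input <- function(rgb, size) {
  if (!identical(dim(rgb)[1:2], c(size, size))) {
    rgb <- EBImage::resize(rgb, w = size, h = size)
    rgb <- clip8(rgb)
  }
  rgb / 255 - 0.5
}

#' Construct a feature-extractor interface object
#'
#' @param name Extractor name.
#' @param input_size Side length (px) the image is resized to.
#' @param dim Output dimensionality.
#' @param forward Function mapping a normalized (size, size, 3) array to a
#'   numeric vector of length `dim`; must be deterministic.
#' @param provenance Free-text description of the training data.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(name, input_size, dim, forward,
                              provenance = "unspecified") {
  structure(list(name = name, input_size = as.integer(input_size),
                 dim = as.integer(dim), forward = forward,
                 provenance = provenance),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor '%s': %d x %d input -> %d features (%s)>\n",
              x$name, x$input_size, x$input_size, x$dim, x$provenance))
  invisible(x)
}

#' Train the bundled desk-scale dermatoscopy extractor
#'
#' Trains a small convolutional network (two strided conv layers, global
#' average pooling, one hidden fully connected layer) to classify phantom
#' dermatoscopy images as AK lesion vs plain skin, then exposes the hidden
#' fully connected layer's activations as a [feature_extractor()]. This is
#' the self-contained stand-in slot of the extractor interface; externally
#' trained checkpoints plug into the same interface via
#' [load_extractor_checkpoint()].
#'
#' @param n_images Total training images (half AK across stages 1-3, half
#'   plain skin).
#' @param params [phantom_params()] used for generation; a small
#'   `derm_size` keeps training light.
#' @param input_size Network input side length.
#' @param fdim Feature (hidden fully connected) dimensionality.
#' @param epochs,lr Adam schedule.
#' @param seed Master seed (generation, init, shuffling).
#' @return A [feature_extractor()] with attribute `"params"` (the weights).
#' @export
train_derm_extractor <- function(n_images = 200L,
                                 params = phantom_params(derm_size = 64L),
                                 input_size = 32L, fdim = 16L, epochs = 15L,
                                 lr = 2e-3, seed = 0L) {
  seeds <- derive_seeds(seed, n_images + 2L)
  labels <- rep(0:1, length.out = n_images)    # 1 = AK lesion present
  xs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    ph <- generate_dermoscopy_phantom(params,
                                      stage = ((i - 1L) %% 3L) + 1L,
                                      seed = seeds[i], hair_count = 0L,
                                      frame = FALSE, ruler = FALSE,
                                      lesion = labels[i] == 1L)
    xs[[i]] <- derm_to_input(ph$clean, input_size)
  }
  pp <- cls_init(seed = seeds[n_images + 1L], fdim = fdim)
  st <- adam_new(pp)
  orders <- with_seed(seeds[n_images + 2L],
                      lapply(seq_len(epochs), function(e) sample(n_images)))
  for (e in seq_len(epochs)) {
    for (i in orders[[e]]) {
      fw <- cls_forward(pp, xs[[i]], want_cache = TRUE)
      p <- softmax_vec(fw$logits)
      d <- p
      d[labels[i] + 1L] <- d[labels[i] + 1L] - 1
      gr <- cls_backward(pp, fw$cache, d)
      up <- adam_step(pp, gr, st, lr = lr)
      pp <- up$params
      st <- up$state
    }
  }
  ex <- feature_extractor(
    name = "phantom_cnn", input_size = input_size, dim = fdim,
    forward = function(x) cls_forward(pp, x)$features,
    provenance = sprintf("trained on %d phantom AK/non-AK images", n_images))
  attr(ex, "params") <- pp
  ex
}

# AK-vs-non-AK prediction with the bundled extractor's underlying classifier
# (used to validate extractor training).
extractor_predict_class <- function(extractor, rgb) {
  pp <- attr(extractor, "params")
  if (is.null(pp)) stopf("extractor carries no classifier weights")
  x <- derm_to_input(rgb, extractor$input_size)
  which.max(cls_forward(pp, x)$logits) - 1L
}

#' Load an externally trained extractor checkpoint
#'
#' Hook for checkpoints trained outside this package (e.g. an AK/non-AK
#' classifier trained on large public dermoscopy archives). The checkpoint
#' is an RDS file holding a list with `name`, `input_size`, `dim`,
#' `provenance` and `params` (weights of the compact classification
#' architecture used by [train_derm_extractor()]).
#'
#' @param path Checkpoint file path.
#' @return A [feature_extractor()].
#' @export
load_extractor_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stopf(paste0("extractor checkpoint not found at '%s'; train one ",
                 "externally and save it for the load_extractor_checkpoint ",
                 "hook, or use train_derm_extractor()"), path)
  }
  ck <- readRDS(path)
  needed <- c("name", "input_size", "dim", "params")
  if (!all(needed %in% names(ck))) {
    stopf("checkpoint must contain: %s", paste(needed, collapse = ", "))
  }
  pp <- ck$params
  ex <- feature_extractor(ck$name, ck$input_size, ck$dim,
                          forward = function(x) cls_forward(pp, x)$features,
                          provenance = ck$provenance %||% "external checkpoint")
  attr(ex, "params") <- pp
  ex
}

#' Save an extractor checkpoint
#'
#' @param extractor A [feature_extractor()] with weights.
#' @param path Destination RDS path.
#' @export
save_extractor_checkpoint <- function(extractor, path) {
  pp <- attr(extractor, "params")
  if (is.null(pp)) stopf("extractor carries no weights to save")
  saveRDS(list(name = extractor$name, input_size = extractor$input_size,
               dim = extractor$dim, provenance = extractor$provenance,
               params = pp), path)
  invisible(path)
}

#' CNN features for one dermatoscopy image
#'
#' Resizes and normalizes the image to the extractor's expected input and
#' returns the extractor's feature activations as named features
#' `derm.nn.f000`, `derm.nn.f001`, ...
#'
#' @param image A [derm_image()] (or (H, W, 3) array).
#' @param extractor A [feature_extractor()].
#' @return Named numeric vector of length `extractor$dim`.
#' @export
cnn_features <- function(image, extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  rgb <- if (inherits(image, "derm_image")) image$rgb else image
  v <- extractor$forward(derm_to_input(rgb, extractor$input_size))
  if (length(v) != extractor$dim) {
    stopf("extractor returned %d values, declared dim is %d", length(v),
          extractor$dim)
  }
  stats::setNames(as.numeric(v),
                  sprintf("derm.nn.f%03d", seq_along(v) - 1L))
}
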