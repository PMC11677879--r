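# Shared machinery for the two compact convolutional networks in the package:
# the encoder-decoder used for HFUS skin-layer segmentation and the small
# dermatoscopy AK/non-AK classifier used as a bundled feature extractor.
# Activations are (H, W, C) arrays; convolution kernels live in
# (C_out, C_in*k*k) matrices consumed by the compiled primitives.

new_conv <- function(cin, cout, k) {
  # He-normal initialization, bias at zero.
  list(
    W = matrix(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
               nrow = cout),
    b = rep(0, cout),
    k = k
  )
}

conv_f <- function(x, p, stride = 1L, dil = 1L, pad = NULL) {
  if (is.null(pad)) pad <- ((p$k - 1L) * dil) %/% 2L
  .conv_fwd(x, p$W, p$b, p$k, stride, dil, pad)
}

# training-time forward: returns list(y, cols); cols feed conv_b
conv_ft <- function(x, p, stride = 1L, dil = 1L, pad = NULL) {
  if (is.null(pad)) pad <- ((p$k - 1L) * dil) %/% 2L
  .conv_fwd_train(x, p$W, p$b, p$k, stride, dil, pad)
}

conv_b <- function(cols, p, dy, xdim, stride = 1L, dil = 1L, pad = NULL) {
  if (is.null(pad)) pad <- ((p$k - 1L) * dil) %/% 2L
  .conv_bwd(cols, p$W, dy, as.integer(xdim), p$k, stride, dil, pad)
}

relu_f <- function(x) {
  x[x < 0] <- 0
  x
}

relu_b <- function(out, dy) dy * (out > 0)

cbind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE),
        dim = c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], 0))))
}

upsample2_f <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2_b <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  dy[io, jo, , drop = FALSE] + dy[io + 1L, jo, , drop = FALSE] +
    dy[io, jo + 1L, , drop = FALSE] + dy[io + 1L, jo + 1L, , drop = FALSE]
}

softmax3 <- function(logits) {
  d <- dim(logits)
  m <- logits[, , 1]
  for (k in seq_len(d[3])[-1]) m <- pmax(m, logits[, , k])
  e <- exp(logits - as.vector(m))    # recycles over the channel dim
  s <- e[, , 1]
  for (k in seq_len(d[3])[-1]) s <- s + e[, , k]
  e / as.vector(s)
}

argmax3 <- function(x) {
  d <- dim(x)
  matrix(max.col(matrix(x, d[1] * d[2], d[3]), ties.method = "first"),
         d[1], d[2])
}

# Pixel-wise cross-entropy plus soft-Dice loss on softmax probabilities.
# `labels` is an (H, W) integer matrix in 0..(K-1). Returns the loss value
# and the gradient w.r.t. the logits.
seg_loss <- function(logits, labels) {
  d <- dim(logits)
  K <- d[3]
  npix <- d[1] * d[2]
  p <- softmax3(logits)
  g <- array(0, dim = d)
  idx <- cbind(c(row(labels)), c(col(labels)), c(labels) + 1L)
  g[idx] <- 1
  ce <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- (p - g) / npix

  eps <- 1e-6
  dp <- array(0, dim = d)
  dice_sum <- 0
  for (kk in seq_len(K)) {
    num <- 2 * sum(p[, , kk] * g[, , kk]) + eps
    den <- sum(p[, , kk]) + sum(g[, , kk]) + eps
    dice_sum <- dice_sum + num / den
    dp[, , kk] <- -(2 * g[, , kk] * den - num) / (den^2 * K)
  }
  dice_loss <- 1 - dice_sum / K
  # route dp through the softmax Jacobian
  pp <- dp * p
  s <- pp[, , 1]
  for (kk in seq_len(K)[-1]) s <- s + pp[, , kk]
  dlogits <- dlogits + p * (dp - as.vector(s))
  list(loss = ce + dice_loss, dlogits = dlogits)
}

# --- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  zero_like <- function(p) lapply(p[c("W", "b")], function(t) t * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      gslot <- if (slot == "W") "dW" else "db"
      g <- grads[[nm]][[gslot]]
      if (slot == "b") g <- as.numeric(g)
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] +
        (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / bc1
      vhat <- state$v[[nm]][[slot]] / bc2
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$W) + length(p$b), 0))
}
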