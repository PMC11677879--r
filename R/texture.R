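# Handcrafted texture descriptors computed on a grayscale image restricted to
# a binary region mask. All functions take `img` (numeric matrix, 0-255) and
# `mask` (logical matrix of the same shape) and return a named numeric
# vector; degenerate regions yield NA values ("explicitly missing") rather
# than errors, so SLEB-absent lesions propagate cleanly.

#' Histogram features of a masked region
#'
#' Mean, standard deviation, skewness, excess kurtosis and Shannon entropy
#' (256 intensity bins, log base 2) of the intensities inside the mask.
#'
#' @param img Numeric matrix with intensities in \[0, 255\].
#' @param mask Logical matrix of the same shape.
#' @return Named vector `mean`, `sd`, `skewness`, `kurtosis`, `entropy`.
#' @export
histogram_features <- function(img, mask) {
  out <- c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
           kurtosis = NA_real_, entropy = NA_real_)
  v <- img[mask]
  if (length(v) == 0) return(out)
  p <- tabulate(pmin(pmax(floor(v), 0), 255) + 1L, 256L) / length(v)
  p <- p[p > 0]
  out["mean"] <- mean(v)
  out["sd"] <- stats::sd(v)
  out["skewness"] <- if (length(v) > 2) e1071::skewness(v) else NA_real_
  out["kurtosis"] <- if (length(v) > 3) e1071::kurtosis(v) else NA_real_
  out["entropy"] <- -sum(p * log2(p))
  out
}

# Quantize 8-bit intensities into `levels` equal-width bins over [0, 256).
# Fixed-range binning keeps codes comparable across regions and lesions.
quantize_gray <- function(img, levels) {
  q <- floor(img * levels / 256)
  pmin(pmax(q, 0), levels - 1)
}

#' Gray-level co-occurrence features of a masked region
#'
#' Builds a symmetric, normalized co-occurrence matrix over pixel pairs that
#' both lie inside the mask, for each offset, and averages contrast,
#' homogeneity, correlation and energy over the offsets. Intensities are
#' quantized into `levels` equal-width bins over the 8-bit range.
#'
#' @param img,mask Image and region mask.
#' @param levels Number of gray levels after quantization.
#' @param offsets List of integer `c(di, dj)` displacement vectors; the
#'   default is distance 1 at 0, 45, 90 and 135 degrees.
#' @return Named vector `contrast`, `homogeneity`, `correlation`, `energy`;
#'   all NA when no offset yields a valid within-mask pair. A constant
#'   region has zero variance, for which `correlation` is defined as 1.
#' @export
glcm_features <- function(img, mask, levels = 32L,
                          offsets = list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L),
                                         c(-1L, -1L))) {
  out <- c(contrast = NA_real_, homogeneity = NA_real_,
           correlation = NA_real_, energy = NA_real_)
  if (sum(mask) < 2) return(out)
  q <- quantize_gray(img, levels)
  h <- nrow(img)
  w <- ncol(img)
  idx <- which(mask)
  ri <- ((idx - 1L) %% h) + 1L
  ci <- ((idx - 1L) %/% h) + 1L
  feats <- vapply(offsets, function(off) {
    r2 <- ri + off[1]
    c2 <- ci + off[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    if (!any(ok)) return(rep(NA_real_, 4))
    j2 <- (c2[ok] - 1L) * h + r2[ok]
    ok2 <- mask[j2]
    if (!any(ok2)) return(rep(NA_real_, 4))
    a <- q[idx[ok][ok2]]
    b <- q[j2[ok2]]
    cnt <- tabulate(a * levels + b + 1L, nbins = levels * levels)
    cm <- matrix(cnt, levels, levels)
    cm <- cm + t(cm)                   # symmetric
    P <- cm / sum(cm)
    lv <- 0:(levels - 1)
    pi_ <- rowSums(P)
    mu <- sum(lv * pi_)
    sg2 <- sum((lv - mu)^2 * pi_)
    dif <- outer(lv, lv, "-")
    contrast <- sum(P * dif^2)
    homog <- sum(P / (1 + abs(dif)))
    corr <- if (sg2 < 1e-12) 1 else
      sum(P * outer(lv - mu, lv - mu)) / sg2
    energy <- sum(P^2)
    c(contrast, homog, corr, energy)
  }, numeric(4))
  if (all(is.na(feats))) return(out)
  out[] <- rowMeans(feats, na.rm = TRUE)
  out
}

#' Uniform local binary pattern features of a masked region
#'
#' Computes 8-neighbour rotation-invariant uniform LBP codes (radius 1) at
#' every pixel whose full 3x3 neighbourhood lies inside the mask, and
#' returns the normalized 10-bin code histogram (codes 0-8 = number of
#' "neighbour >= center" bits for uniform patterns, bin 9 = non-uniform).
#' A constant region maps entirely to the flat code 8 (ties count as 1).
#'
#' @param img,mask Image and region mask.
#' @param radius Neighbourhood radius in px (the 8 sampling points are the
#'   discrete ring at Chebyshev distance `radius`).
#' @return Named vector `u0` ... `u8`, `nonuniform`, summing to 1; all NA
#'   when the mask has no interior pixel at the given radius.
#' @export
lbp_features <- function(img, mask, radius = 1L, n_points = 8L) {
  if (n_points != 8L) stopf("only the 8-point neighbourhood is implemented")
  nm <- c(paste0("u", 0:8), "nonuniform")
  out <- stats::setNames(rep(NA_real_, 10), nm)
  h <- nrow(img)
  w <- ncol(img)
  r <- as.integer(radius)
  # counter-clockwise ring starting at angle 0 (east)
  offs <- list(c(0, r), c(-r, r), c(-r, 0), c(-r, -r), c(0, -r), c(r, -r),
               c(r, 0), c(r, r))
  idx <- which(mask)
  ri <- ((idx - 1L) %% h) + 1L
  ci <- ((idx - 1L) %/% h) + 1L
  interior <- rep(TRUE, length(idx))
  for (off in offs) {
    r2 <- ri + off[1]
    c2 <- ci + off[2]
    inb <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    interior <- interior & inb
    interior[inb] <- interior[inb] & mask[(c2[inb] - 1L) * h + r2[inb]]
  }
  if (!any(interior)) return(out)
  ric <- ri[interior]
  cic <- ci[interior]
  center <- img[(cic - 1L) * h + ric]
  bits <- vapply(offs, function(off) {
    img[(cic + off[2] - 1L) * h + (ric + off[1])] >= center
  }, logical(length(center)))
  bits <- matrix(bits, ncol = 8)
  trans <- rowSums(bits != bits[, c(2:8, 1), drop = FALSE])
  ones <- rowSums(bits)
  code <- ifelse(trans <= 2, ones, 9L)
  out[] <- tabulate(code + 1L, 10L) / length(code)
  out
}

# --- scattering-wavelet transform -------------------------------------------

# Fourier-domain Gabor filter bank for an M x N patch: J dyadic scales,
# L orientations, plus a Gaussian low pass at scale J.
scattering_filters <- function(M, N, J = 2L, L = 6L) {
  wx <- 2 * pi * (c(0:(M - 1)) - ifelse(0:(M - 1) >= M / 2, M, 0)) / M
  wy <- 2 * pi * (c(0:(N - 1)) - ifelse(0:(N - 1) >= N / 2, N, 0)) / N
  WX <- matrix(wx, M, N)
  WY <- matrix(wy, M, N, byrow = TRUE)
  psis <- list()
  for (j in 0:(J - 1)) {
    xi <- 3 * pi / 4 / 2^j
    sg <- 0.8 * 2^j
    for (l in 0:(L - 1)) {
      th <- pi * l / L
      hat <- exp(-sg^2 * ((WX - xi * cos(th))^2 + (WY - xi * sin(th))^2) / 2)
      psis[[sprintf("j%d_l%d", j, l)]] <- hat
    }
  }
  phi <- exp(-(0.8 * 2^J)^2 * (WX^2 + WY^2) / 2)
  list(psis = psis, phi = phi, J = J, L = L)
}

fft_conv_mod <- function(Fx, hat) {
  Mod(stats::fft(Fx * hat, inverse = TRUE)) / length(Fx)
}

#' Scattering-wavelet features of a masked region
#'
#' Order-0/1/2 scattering coefficients of the mask bounding-box patch
#' (background pixels replaced by the in-mask mean intensity), spatially
#' averaged to one value per scattering path. First-order paths run over `J`
#' dyadic scales and `L` orientations; second-order paths over scale pairs
#' `j2 > j1`. Coefficients of order >= 1 are means of complex moduli and
#' hence non-negative.
#'
#' @param img,mask Image and region mask.
#' @param J,L Number of scales and orientations.
#' @param min_size Minimal bounding-box side in px; smaller regions return
#'   all-NA (missing).
#' @return Named vector: `s0`, `s1.j<j>l<l>`, `s2.j<j1>l<l1>.j<j2>l<l2>`.
#' @export
scattering_features <- function(img, mask, J = 2L, L = 6L, min_size = 16L) {
  nm <- "s0"
  for (j in 0:(J - 1)) nm <- c(nm, sprintf("s1.j%dl%d", j, 0:(L - 1)))
  for (j1 in 0:(J - 2)) for (l1 in 0:(L - 1)) for (j2 in (j1 + 1):(J - 1)) {
    nm <- c(nm, sprintf("s2.j%dl%d.j%dl%d", j1, l1, j2, 0:(L - 1)))
  }
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (!any(mask)) return(out)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  M <- rr[2] - rr[1] + 1L
  N <- cc[2] - cc[1] + 1L
  if (M < min_size || N < min_size) return(out)
  patch <- img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sub <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  patch[!sub] <- mean(patch[sub])
  patch <- patch / 255
  fl <- scattering_filters(M, N, J, L)
  Fx <- stats::fft(patch)
  out["s0"] <- mean(Re(stats::fft(Fx * fl$phi, inverse = TRUE))) / (M * N)
  for (j1 in 0:(J - 1)) {
    for (l1 in 0:(L - 1)) {
      u1 <- fft_conv_mod(Fx, fl$psis[[sprintf("j%d_l%d", j1, l1)]])
      out[sprintf("s1.j%dl%d", j1, l1)] <- mean(u1)
      if (j1 < J - 1) {
        Fu <- stats::fft(u1)
        for (j2 in (j1 + 1):(J - 1)) {
          for (l2 in 0:(L - 1)) {
            u2 <- fft_conv_mod(Fu, fl$psis[[sprintf("j%d_l%d", j2, l2)]])
            out[sprintf("s2.j%dl%d.j%dl%d", j1, l1, j2, l2)] <- mean(u2)
          }
        }
      }
    }
  }
  out
}

# One call bundling the full texture family set for a region.
texture_features <- function(img, mask, glcm_levels = 32L, lbp_radius = 1L,
                             scat_J = 2L, scat_L = 6L) {
  hf <- histogram_features(img, mask)
  gf <- glcm_features(img, mask, glcm_levels)
  lf <- lbp_features(img, mask, lbp_radius)
  sf <- scattering_features(img, mask, scat_J, scat_L)
  c(stats::setNames(hf, paste0("hist.", names(hf))),
    stats::setNames(gf, paste0("glcm.", names(gf))),
    stats::setNames(lf, paste0("lbp.", names(lf))),
    stats::setNames(sf, paste0("scat.", names(sf))))
}
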