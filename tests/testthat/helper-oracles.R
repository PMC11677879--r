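# Independent brute-force oracles used to pin down the texture and
# morphology implementations, plus small cached fixtures. The oracles use
# explicit per-pixel enumeration and share nothing with the vectorized
# implementations beyond the documented conventions.

# --- GLCM by explicit pair enumeration --------------------------------------

glcm_oracle <- function(img, mask, levels = 32L,
                        offsets = list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L),
                                       c(-1L, -1L))) {
  q <- floor(img * levels / 256)
  q[q > levels - 1] <- levels - 1
  q[q < 0] <- 0
  h <- nrow(img)
  w <- ncol(img)
  per_off <- lapply(offsets, function(off) {
    P <- matrix(0, levels, levels)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        i2 <- i + off[1]
        j2 <- j + off[2]
        if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w &&
            mask[i, j] && mask[i2, j2]) {
          P[q[i, j] + 1, q[i2, j2] + 1] <- P[q[i, j] + 1, q[i2, j2] + 1] + 1
          P[q[i2, j2] + 1, q[i, j] + 1] <- P[q[i2, j2] + 1, q[i, j] + 1] + 1
        }
      }
    }
    if (sum(P) == 0) return(rep(NA_real_, 4))
    P <- P / sum(P)
    lv <- 0:(levels - 1)
    pi_ <- rowSums(P)
    mu <- sum(lv * pi_)
    sg2 <- sum((lv - mu)^2 * pi_)
    dif <- outer(lv, lv, "-")
    c(contrast = sum(P * dif^2),
      homogeneity = sum(P / (1 + abs(dif))),
      correlation = if (sg2 < 1e-12) 1 else
        sum(P * outer(lv - mu, lv - mu)) / sg2,
      energy = sum(P^2))
  })
  m <- do.call(cbind, per_off)
  if (all(is.na(m))) return(stats::setNames(rep(NA_real_, 4),
                                            c("contrast", "homogeneity",
                                              "correlation", "energy")))
  rowMeans(m, na.rm = TRUE)
}

# --- LBP by per-pixel neighbourhood thresholding ----------------------------

lbp_oracle <- function(img, mask, radius = 1L) {
  h <- nrow(img)
  w <- ncol(img)
  r <- radius
  offs <- list(c(0, r), c(-r, r), c(-r, 0), c(-r, -r), c(0, -r), c(r, -r),
               c(r, 0), c(r, r))
  codes <- integer(0)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      bits <- logical(8)
      ok <- TRUE
      for (b in 1:8) {
        i2 <- i + offs[[b]][1]
        j2 <- j + offs[[b]][2]
        if (i2 < 1 || i2 > h || j2 < 1 || j2 > w || !mask[i2, j2]) {
          ok <- FALSE
          break
        }
        bits[b] <- img[i2, j2] >= img[i, j]
      }
      if (!ok) next
      transitions <- sum(bits != c(bits[-1], bits[1]))
      codes <- c(codes, if (transitions <= 2) sum(bits) else 9L)
    }
  }
  if (!length(codes)) {
    return(stats::setNames(rep(NA_real_, 10),
                           c(paste0("u", 0:8), "nonuniform")))
  }
  stats::setNames(tabulate(codes + 1L, 10L) / length(codes),
                  c(paste0("u", 0:8), "nonuniform"))
}

# --- perimeter by explicit edge counting ------------------------------------

perimeter_oracle <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  per <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        i2 <- i + d[1]
        j2 <- j + d[2]
        if (i2 < 1 || i2 > h || j2 < 1 || j2 > w || !mask[i2, j2]) {
          per <- per + 1L
        }
      }
    }
  }
  per
}

# --- cached fixtures (built once per test run) ------------------------------

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_hfus_phantom <- function() {
  fixture("hfus_ph", function() {
    generate_hfus_phantom(phantom_params(), stage = 2, seed = 101,
                          force_sleb = TRUE)
  })
}

small_derm_phantom <- function() {
  fixture("derm_ph", function() {
    generate_dermoscopy_phantom(phantom_params(derm_size = 128L), stage = 2,
                                seed = 77, hair_count = 6L)
  })
}

# a tiny synthetic feature table with two informative and several noise
# features, grouped by patient
toy_feature_table <- function(n_patients = 18L, per_patient = 3L,
                              seed = 42L, informative = TRUE) {
  set.seed(seed)
  n <- n_patients * per_patient
  stage <- rep(rep(1:3, length.out = per_patient), n_patients)
  tab <- data.frame(
    patient_id = sprintf("P%02d", rep(seq_len(n_patients),
                                      each = per_patient)),
    lesion_id = sprintf("L%03d", seq_len(n)),
    stage = stage, check.names = FALSE)
  if (informative) {
    tab[["hfus.morph.entry_echo.thickness_q3"]] <-
      2 * stage + rnorm(n, 0, 0.8)
    tab[["hfus.hist.entry_echo.entropy"]] <- -stage + rnorm(n, 0, 1.2)
  }
  for (j in 1:8) {
    tab[[sprintf("hfus.glcm.sleb.noise%d", j)]] <- rnorm(n)
  }
  tab
}
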