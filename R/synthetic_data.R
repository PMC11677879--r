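#' Phantom generator parameters
#'
#' Bundles every tunable of the HFUS and dermatoscopy phantom generators.
#' Defaults encode the stage trends the staging problem rests on: entry-echo
#' thickness and boundary roughness grow with AK stage, the SLEB is a low
#' echogenic band whose mean intensity drops and whose speckle smooths out
#' with stage (stage 1 lesions show the most SLEB contrast), and the
#' dermatoscopic surface brightens towards the white-yellow keratotic look of
#' stage 3. Per-stage fields are length-3 vectors indexed by stage; scalars
#' are recycled.
#'
#' @param ... Named overrides of any default listed below.
#' @return A validated object of class `phantom_params`.
#' @details Defaults (all lengths in px, intensities on the 8-bit 0-255
#' scale): HFUS canvas 128 x 256 (depth x lateral; a desk-scale stand-in for
#' the 224 x 512 cropped clinical format, selectable via
#' `hfus_height`/`hfus_width`), entry-echo thickness mean (8, 12, 16) sd 2,
#' boundary roughness amplitude (1, 2.5, 4), SLEB presence probability 0.85,
#' SLEB thickness mean 22 sd 5, layer mean echogenicity: background 8, entry
#' echo 190, SLEB (55, 45, 35), dermis 120; multiplicative speckle sd
#' fractions: background 0.10, entry echo (0.10, 0.16, 0.22), SLEB
#' (0.35, 0.27, 0.20), dermis 0.25; dermis reference band depth 50.
#' Dermatoscopy canvas 512 x 512 (stand-in for 3024 x 4032, selectable via
#' `derm_size`), per-stage lesion base color, scale-texture amplitude
#' (6, 12, 18), keratotic follicle count (0, 25, 40), hair count range
#' (5, 15), frame corner radius fraction 0.30.
#' @export
phantom_params <- function(...) {
  p <- list(
    hfus_height = 128L, hfus_width = 256L,
    entry_start_depth = 5,
    entry_thickness_mean = c(8, 12, 16),
    entry_thickness_sd = c(2, 2, 2),
    entry_roughness = c(1, 2.5, 4),
    sleb_presence = 0.85,
    sleb_thickness_mean = 22,
    sleb_thickness_sd = 5,
    mean_background = 8,
    mean_entry = 190,
    mean_sleb = c(55, 45, 35),
    mean_dermis = 120,
    speckle_background = 0.10,
    speckle_entry = c(0.10, 0.16, 0.22),
    speckle_sleb = c(0.35, 0.27, 0.20),
    speckle_dermis = 0.25,
    dermis_band_depth = 50,
    derm_size = 512L,
    derm_skin_color = c(225, 190, 180),
    derm_base_color = rbind(c(200, 140, 135),
                            c(215, 165, 130),
                            c(235, 215, 175)),
    derm_texture_amp = c(6, 12, 18),
    derm_follicle_count = c(0, 25, 40),
    derm_hair_count_range = c(5, 15),
    derm_hair_width_range = c(3, 9),
    derm_frame_radius_frac = 0.30,
    derm_ruler_prob = 0.5
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stopf("unknown phantom parameter(s): %s",
                         paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  validate_phantom_params(structure(p, class = "phantom_params"))
}

validate_phantom_params <- function(p) {
  pos <- c("entry_thickness_mean", "entry_roughness", "sleb_thickness_mean",
           "derm_texture_amp")
  for (nm in pos) {
    if (any(p[[nm]] <= 0)) stopf("'%s' must be strictly positive", nm)
  }
  if (any(p$entry_thickness_sd < 0) || p$sleb_thickness_sd < 0) {
    stopf("thickness sd must be non-negative")
  }
  echo <- c(p$mean_background, p$mean_entry, p$mean_sleb, p$mean_dermis)
  if (any(echo < 0 | echo > 255)) stopf("echogenicity means must be in [0, 255]")
  if (p$sleb_presence < 0 || p$sleb_presence > 1) {
    stopf("sleb_presence must be a probability")
  }
  m <- per_stage(p$entry_thickness_mean)
  if (m[3] <= m[1]) {
    stopf("stage-3 entry-echo thickness mean must exceed the stage-1 mean")
  }
  if (max(per_stage(p$mean_sleb)) >= min(per_stage(p$mean_dermis))) {
    stopf("SLEB mean echogenicity must lie below the dermis mean (low echogenic band)")
  }
  p
}

# per-stage lookup with scalar recycling
per_stage <- function(x, stage = NULL) {
  x <- rep_len(x, 3)
  if (is.null(stage)) x else x[stage]
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_params: HFUS %d x %d px, derm %d x %d px,\n",
    "  entry-echo thickness mean %s px, SLEB mean intensity %s>\n"),
    x$hfus_height, x$hfus_width, x$derm_size, x$derm_size,
    paste(per_stage(x$entry_thickness_mean), collapse = "/"),
    paste(per_stage(x$mean_sleb), collapse = "/")))
  invisible(x)
}

# Smooth lateral profile: unit-sd low-frequency noise along columns.
smooth_profile <- function(w, sigma = 6) {
  n <- stats::rnorm(w + 8 * sigma)
  k <- stats::dnorm(seq(-3 * sigma, 3 * sigma), sd = sigma)
  s <- stats::filter(n, k / sum(k), sides = 2)
  s <- s[(4 * sigma + 1):(4 * sigma + w)]
  s <- s - mean(s)
  sdv <- stats::sd(s)
  if (sdv < 1e-12) rep(0, w) else s / sdv
}

# Normalized Rayleigh speckle field (unit mean) of the given size.
rayleigh_unit <- function(n) {
  sqrt(-2 * log(stats::runif(n))) / sqrt(pi / 2)
}

#' Generate one HFUS phantom scan with ground-truth layer masks
#'
#' Draws a layered speckle image: a dark coupling-gel band on top, a bright
#' entry echo of stage-dependent thickness and boundary roughness, optionally
#' a hypoechoic SLEB beneath it, and dermis filling the remaining depth.
#' Speckle is multiplicative Rayleigh-type noise around each layer's mean
#' intensity, clipped to 8 bits; a speckle fraction of zero yields an image
#' that is exactly piecewise constant at the layer means.
#'
#' @param params A [phantom_params()] object.
#' @param stage AK stage in 1..3.
#' @param seed Integer seed; identical `(params, stage, seed)` give
#'   bit-identical output.
#' @param force_sleb Logical or `NA`; `NA` (default) draws SLEB presence from
#'   `params$sleb_presence`, otherwise forces presence/absence.
#' @return A list with elements `scan` ([hfus_scan()]) and `masks`
#'   ([layer_mask_set()]); the dermis-reference mask is the band of
#'   `params$dermis_band_depth` px directly below the SLEB (or entry echo when
#'   SLEB is absent).
#' @export
generate_hfus_phantom <- function(params = phantom_params(), stage, seed = 1L,
                                  force_sleb = NA) {
  stopifnot(inherits(params, "phantom_params"))
  if (!stage %in% 1:3) stopf("stage must be 1, 2 or 3")
  with_seed(seed, {
    H <- params$hfus_height
    W <- params$hfus_width
    for (attempt in seq_len(100L)) {
      start <- pmax(1, round(params$entry_start_depth + 1.5 * smooth_profile(W)))
      t0 <- stats::rnorm(1, per_stage(params$entry_thickness_mean, stage),
                         per_stage(params$entry_thickness_sd, stage))
      rough <- per_stage(params$entry_roughness, stage)
      phase <- stats::runif(1, 0, 2 * pi)
      freq <- stats::runif(1, 1.5, 3.5)
      th <- t0 + rough * sin(2 * pi * freq * seq_len(W) / W + phase) +
        0.6 * rough * smooth_profile(W)
      th <- pmax(2, round(th))
      sleb_here <- if (is.na(force_sleb)) {
        stats::runif(1) < params$sleb_presence
      } else {
        isTRUE(force_sleb)
      }
      sth <- if (sleb_here) {
        s0 <- stats::rnorm(1, params$sleb_thickness_mean,
                           params$sleb_thickness_sd)
        pmax(3, round(s0 + 2 * smooth_profile(W)))
      } else {
        rep(0L, W)
      }
      deepest <- max(start + th + sth) + params$dermis_band_depth
      if (deepest <= H - 2) break
      if (attempt == 100L) {
        stopf("layer thickness draws exceed the %d px image height after 100 attempts", H)
      }
    }

    entry <- matrix(FALSE, H, W)
    sleb <- matrix(FALSE, H, W)
    dermis_ref <- matrix(FALSE, H, W)
    region <- matrix(1L, H, W)  # 1 bg, 2 entry, 3 sleb, 4 dermis
    rows <- seq_len(H)
    for (j in seq_len(W)) {
      e0 <- start[j]
      e1 <- e0 + th[j] - 1L
      entry[e0:e1, j] <- TRUE
      region[rows >= e0 & rows <= e1, j] <- 2L
      bottom <- e1
      if (sth[j] > 0) {
        s1 <- e1 + sth[j]
        sleb[(e1 + 1L):s1, j] <- TRUE
        region[rows > e1 & rows <= s1, j] <- 3L
        bottom <- s1
      }
      region[rows > bottom, j] <- 4L
      dermis_ref[(bottom + 1L):(bottom + params$dermis_band_depth), j] <- TRUE
    }

    mu <- c(params$mean_background, params$mean_entry,
            per_stage(params$mean_sleb, stage), params$mean_dermis)[region]
    sfrac <- c(params$speckle_background,
               per_stage(params$speckle_entry, stage),
               per_stage(params$speckle_sleb, stage),
               params$speckle_dermis)[region]
    img <- mu * (1 + sfrac * (rayleigh_unit(H * W) - 1))
    img <- matrix(round(clip8(img)), H, W)

    list(scan = hfus_scan(img),
         masks = layer_mask_set(entry, sleb, dermis_ref))
  })
}

# --- dermatoscopy phantom ----------------------------------------------------

smooth_field <- function(h, w, sigma = 8) {
  f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = sigma)
  f <- f - mean(f)
  sdv <- stats::sd(as.numeric(f))
  if (sdv < 1e-12) matrix(0, h, w) else f / sdv
}

stamp_disks <- function(mask, ci, cj, radius) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(radius)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= radius^2, ]
  ii <- rep(round(ci), each = nrow(off)) + off$di
  jj <- rep(round(cj), each = nrow(off)) + off$dj
  ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
  mask[cbind(ii[ok], jj[ok])] <- TRUE
  mask
}

rounded_rect_mask <- function(s, radius) {
  xx <- matrix(seq_len(s), s, s)            # rows
  yy <- matrix(seq_len(s), s, s, byrow = TRUE)
  cx <- pmin(pmax(xx, 1 + radius), s - radius)
  cy <- pmin(pmax(yy, 1 + radius), s - radius)
  (xx - cx)^2 + (yy - cy)^2 <= radius^2
}

#' Generate one dermatoscopy phantom with artifact ground truth
#'
#' Composes a clean stage-textured lesion image with the acquisition
#' artifacts typical of dermatoscopic photographs: a dark round-corner frame,
#' dark and light hairs rendered as random quadratic Bezier strokes 3-9 px
#' wide, and optional ruler tick marks. Ground-truth masks exactly cover the
#' injected artifacts, so preprocessing steps can be scored against them.
#'
#' @param params A [phantom_params()] object.
#' @param stage AK stage in 1..3 (drives lesion color, scale-texture
#'   amplitude and keratotic follicle count).
#' @param seed Integer seed.
#' @param hair_count Number of hairs; `NULL` draws from
#'   `params$derm_hair_count_range`. Must be >= 0.
#' @param frame Draw the round-corner frame?
#' @param ruler Draw ruler marks? `NULL` draws with probability
#'   `params$derm_ruler_prob` when `frame` is `TRUE`, otherwise omits them.
#' @param lesion Draw the AK lesion? `FALSE` yields plain skin (used to train
#'   the bundled AK/non-AK feature extractor).
#' @return A list: `image` ([derm_image()], the composite), `clean` (the
#'   artifact-free (H, W, 3) array), `frame_mask`, `hair_mask` (hairs plus
#'   ruler marks; disjoint from `frame_mask`).
#' @export
generate_dermoscopy_phantom <- function(params = phantom_params(), stage,
                                        seed = 1L, hair_count = NULL,
                                        frame = TRUE, ruler = NULL,
                                        lesion = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  if (!stage %in% 1:3) stopf("stage must be 1, 2 or 3")
  if (!is.null(hair_count) && hair_count < 0) {
    stopf("hair_count must be >= 0")
  }
  with_seed(seed, {
    s <- params$derm_size
    base <- array(0, dim = c(s, s, 3))
    for (ch in 1:3) {
      # low-frequency tone variation plus fine skin grain / sensor noise
      base[, , ch] <- params$derm_skin_color[ch] + 4 * smooth_field(s, s, 10) +
        stats::rnorm(s * s, sd = 2.5)
    }

    if (lesion) {
      xx <- matrix(seq_len(s), s, s)
      yy <- matrix(seq_len(s), s, s, byrow = TRUE)
      dist <- sqrt((xx - s / 2)^2 + (yy - s / 2)^2)
      wgt <- stats::plogis((0.35 * s - dist) / (0.02 * s))
      tex <- per_stage(params$derm_texture_amp, stage) * smooth_field(s, s, 3)
      for (ch in 1:3) {
        col <- per_stage(params$derm_base_color[, ch], stage)
        base[, , ch] <- base[, , ch] * (1 - wgt) + (col + tex) * wgt
      }
      nfol <- per_stage(params$derm_follicle_count, stage)
      if (nfol > 0) {
        ang <- stats::runif(nfol, 0, 2 * pi)
        rad <- 0.30 * s * sqrt(stats::runif(nfol))
        fi <- s / 2 + rad * cos(ang)
        fj <- s / 2 + rad * sin(ang)
        fcol <- c(240, 230, 170)
        for (f in seq_len(nfol)) {
          m <- stamp_disks(matrix(FALSE, s, s), fi[f], fj[f],
                           stats::runif(1, 2, 4))
          for (ch in 1:3) {
            plane <- base[, , ch]
            plane[m] <- 0.25 * plane[m] + 0.75 * fcol[ch]
            base[, , ch] <- plane
          }
        }
      }
    }
    clean <- round(clip8(base))    # 8-bit: survives PNG round trips exactly

    composite <- clean
    hair_mask <- matrix(FALSE, s, s)
    nh <- hair_count %||% sample(
      params$derm_hair_count_range[1]:params$derm_hair_count_range[2], 1)
    if (nh > 0) {
      for (h in seq_len(nh)) {
        p0 <- stats::runif(2, 0.05 * s, 0.95 * s)
        p1 <- stats::runif(2, 0.05 * s, 0.95 * s)
        p2 <- stats::runif(2, 0.05 * s, 0.95 * s)
        tt <- seq(0, 1, length.out = 4L * s %/% 2)
        bi <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
        bj <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
        wdt <- sample(params$derm_hair_width_range[1]:
                        params$derm_hair_width_range[2], 1)
        m <- stamp_disks(matrix(FALSE, s, s), bi, bj, wdt / 2)
        dark <- stats::runif(1) < 0.6
        hcol <- if (dark) c(45, 35, 28) else c(225, 220, 205)
        for (ch in 1:3) {
          plane <- composite[, , ch]
          plane[m] <- 0.08 * plane[m] + 0.92 * hcol[ch]
          composite[, , ch] <- plane
        }
        hair_mask <- hair_mask | m
      }
    }

    if (is.null(ruler)) {
      ruler <- frame && stats::runif(1) < params$derm_ruler_prob
    }
    if (ruler) {
      jx <- round(0.06 * s)
      for (yc in round(seq(0.2 * s, 0.8 * s, length.out = 10))) {
        ii <- yc:min(yc + 15, s)
        jjr <- jx:min(jx + 2, s)
        composite[ii, jjr, ] <- 35
        hair_mask[ii, jjr] <- TRUE
      }
    }

    frame_mask <- matrix(FALSE, s, s)
    if (frame) {
      fov <- rounded_rect_mask(s, round(params$derm_frame_radius_frac * s))
      frame_mask <- !fov
      for (ch in 1:3) {
        plane <- composite[, , ch]
        plane[frame_mask] <- 10
        composite[, , ch] <- plane
      }
      hair_mask <- hair_mask & fov
    }

    list(image = derm_image(round(clip8(composite))), clean = clean,
         frame_mask = frame_mask, hair_mask = hair_mask)
  })
}

#' Generate a multi-patient phantom cohort
#'
#' Builds paired HFUS and dermatoscopy phantoms for a whole cohort. Lesions
#' are distributed over patients round-robin after a seeded shuffle, so a
#' single patient typically holds lesions of several stages, as in clinical
#' AK series.
#'
#' @param n_patients Number of patients (>= 1).
#' @param class_counts Integer vector (n1, n2, n3) of lesions per stage. The
#'   default mirrors a published clinical AK series: 92 stage-1, 42 stage-2
#'   and 27 stage-3 lesions.
#' @param params A [phantom_params()] object.
#' @param seed Integer master seed; every lesion's images derive from it.
#' @param modalities Subset of `c("hfus", "derm")`; generating HFUS-only
#'   cohorts keeps large simulation studies light.
#' @return An object of class `ak_cohort`: a list with `params`, `patients`
#'   (ids) and `lesions`, each lesion carrying `patient_id`, `lesion_id`,
#'   `stage` and the requested modalities (`hfus` = list(scan, masks);
#'   `derm` = the [generate_dermoscopy_phantom()] value).
#' @export
generate_cohort <- function(n_patients, class_counts = c(92L, 42L, 27L),
                            params = phantom_params(), seed = 1L,
                            modalities = c("hfus", "derm")) {
  if (any(class_counts < 0)) stopf("class counts must be non-negative")
  n <- sum(class_counts)
  if (n_patients < 1 || n < n_patients) {
    stopf("need n1+n2+n3 >= n_patients >= 1 (got %d lesions, %d patients)",
          n, n_patients)
  }
  if (length(modalities)) {
    modalities <- match.arg(modalities, several.ok = TRUE)
  }
  if (identical(as.integer(class_counts), c(92L, 42L, 27L))) {
    message("default class counts 92/42/27 sum to 161 lesions; the clinical ",
            "series these defaults mirror reports a total of 162 pairs - the ",
            "one-pair discrepancy is kept as printed, not resolved")
  }
  stages <- rep(1:3, times = class_counts)
  seeds <- derive_seeds(seed, 2L * n + 1L)
  stages <- with_seed(seeds[2L * n + 1L], sample(stages))
  patients <- sprintf("P%03d", seq_len(n_patients))
  lesions <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- patients[((i - 1L) %% n_patients) + 1L]
    lid <- sprintf("L%03d", i)
    les <- list(patient_id = pid, lesion_id = lid, stage = stages[i])
    if ("hfus" %in% modalities) {
      hf <- generate_hfus_phantom(params, stages[i], seed = seeds[2L * i - 1L])
      hf$scan$patient_id <- pid
      hf$scan$lesion_id <- lid
      les$hfus <- hf
    }
    if ("derm" %in% modalities) {
      dm <- generate_dermoscopy_phantom(params, stages[i],
                                        seed = seeds[2L * i])
      dm$image$patient_id <- pid
      dm$image$lesion_id <- lid
      les$derm <- dm
    }
    lesions[[i]] <- les
  }
  structure(list(params = params, patients = patients, lesions = lesions),
            class = "ak_cohort")
}

#' @export
print.ak_cohort <- function(x, ...) {
  st <- vapply(x$lesions, `[[`, 0, "stage")
  cat(sprintf("<ak_cohort: %d patients, %d lesions (stage 1/2/3: %d/%d/%d)>\n",
              length(x$patients), length(x$lesions), sum(st == 1),
              sum(st == 2), sum(st == 3)))
  invisible(x)
}

#' Per-lesion stage labels and patient ids of a cohort
#'
#' @param cohort An `ak_cohort`.
#' @return `cohort_stages`: integer vector of stage labels;
#'   `cohort_patients`: character vector of patient ids, both one entry per
#'   lesion in cohort order.
#' @export
cohort_stages <- function(cohort) {
  vapply(cohort$lesions, `[[`, 0, "stage")
}

#' @rdname cohort_stages
#' @export
cohort_patients <- function(cohort) {
  vapply(cohort$lesions, `[[`, "", "patient_id")
}
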