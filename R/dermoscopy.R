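# Dermatoscopic preprocessing and feature extraction: frame/background
# removal, dual-polarity hair and ruler removal with inpainting, RGB+HSV
# channel decomposition, per-channel handcrafted texture features, and a
# pluggable CNN feature-extractor interface.

derm_gray <- function(rgb) (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3

# local standard deviation in a (2r+1)^2 box; a cheap sharpness measure
local_sd <- function(x, r = 2L) {
  k <- matrix(1 / (2 * r + 1)^2, 2 * r + 1, 2 * r + 1)
  m <- EBImage::filter2(x, k)
  m2 <- EBImage::filter2(x^2, k)
  sqrt(pmax(m2 - m^2, 0))
}

#' Segment the valid (informative) region of a dermatoscopy image
#'
#' Removes the dark round-corner frame and blurred background: contrast
#' stretch (intensity adjustment), dark-pixel thresholding for the frame,
#' then 2-cluster fuzzy c-means on (intensity, local sharpness) to drop a
#' blurred-background cluster when one clearly exists. The largest component
#' containing (or nearest to) the image center is kept and hole-filled.
#'
#' @param image A [derm_image()].
#' @param dark_frac Dark threshold as a fraction of the stretched range.
#' @param blur_ratio The low-sharpness fuzzy c-means cluster is dropped as
#'   blurred background only when its raw sharpness center falls below
#'   `blur_ratio` times the median sharpness of the whole candidate region.
#'   Optical blur suppresses the fine grain present everywhere in a focused
#'   photograph by an order of magnitude, while smooth-but-focused skin
#'   stays near the image median, so the guard never discards plain skin.
#' @param fcm_sample Number of pixels subsampled for clustering (centers are
#'   then applied to all pixels); clustering is internally seeded, so the
#'   result is deterministic.
#' @return Logical valid-region mask.
#' @export
remove_frame_and_background <- function(image, dark_frac = 0.06,
                                        blur_ratio = 0.35,
                                        fcm_sample = 4000L) {
  stopifnot(inherits(image, "derm_image"))
  g <- derm_gray(image$rgb)
  qs <- stats::quantile(g, c(0.01, 0.99), names = FALSE)
  if (qs[2] - qs[1] < 1) stopf("no valid region: image is flat")
  g2 <- clip8((g - qs[1]) / (qs[2] - qs[1]) * 255)
  dark <- g2 < dark_frac * 255
  valid <- !dark
  if (!any(valid)) stopf("no valid region after frame thresholding")

  # cap sharpness at a robust multiple of its median: hair and frame edges
  # are extreme outliers that would otherwise dominate the clustering
  sharp <- local_sd(g2)
  med_sharp <- stats::median(sharp[valid])
  cap <- max(5 * med_sharp, 1e-9)
  sharp_c <- pmin(sharp, cap)
  feat <- cbind(intensity = as.numeric(g2[valid]) / 255,
                sharpness = as.numeric(sharp_c[valid]) / cap)
  n <- nrow(feat)
  take <- with_seed(1L, sample(n, min(fcm_sample, n)))
  cm <- with_seed(1L, e1071::cmeans(feat[take, , drop = FALSE], centers = 2,
                                    iter.max = 50))
  ctr <- cm$centers
  blur_cl <- which.min(ctr[, "sharpness"])
  if (ctr[blur_cl, "sharpness"] * cap < blur_ratio * med_sharp) {
    d1 <- (feat[, 1] - ctr[1, 1])^2 + (feat[, 2] - ctr[1, 2])^2
    d2 <- (feat[, 1] - ctr[2, 1])^2 + (feat[, 2] - ctr[2, 2])^2
    assign_blur <- if (blur_cl == 1L) d1 < d2 else d2 < d1
    vidx <- which(valid)
    valid[vidx[assign_blur]] <- FALSE
  }
  if (!any(valid)) stopf("no valid region after background clustering")

  lab <- EBImage::bwlabel(valid)
  h <- nrow(lab)
  w <- ncol(lab)
  center_lab <- lab[round(h / 2), round(w / 2)]
  keep <- if (center_lab > 0) center_lab else which.max(tabulate(lab[lab > 0]))
  m <- EBImage::fillHull(lab == keep) > 0
  if (!any(m)) stopf("no valid region")
  m
}

# shift-based grayscale erosion/dilation along a line structuring element
line_offsets <- function(length, angle) {
  half <- (length - 1) / 2
  t <- seq(-half, half)
  a <- angle * pi / 180
  unique(cbind(round(-t * sin(a)), round(t * cos(a))))
}

shift_mat <- function(x, di, dj, fill) {
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(fill, h, w)
  si <- max(1, 1 - di):min(h, h - di)
  sj <- max(1, 1 - dj):min(w, w - dj)
  out[si + di, sj + dj] <- x[si, sj, drop = FALSE]
  out
}

gray_morph_line <- function(x, length, angle, op = c("erode", "dilate")) {
  op <- match.arg(op)
  offs <- line_offsets(length, angle)
  fill <- if (op == "erode") Inf else -Inf
  acc <- NULL
  for (r in seq_len(nrow(offs))) {
    s <- shift_mat(x, offs[r, 1], offs[r, 2], fill)
    acc <- if (is.null(acc)) s else if (op == "erode") pmin(acc, s) else
      pmax(acc, s)
  }
  acc
}

line_closing <- function(x, length, angle) {
  gray_morph_line(gray_morph_line(x, length, angle, "dilate"), length, angle,
                  "erode")
}

line_opening <- function(x, length, angle) {
  gray_morph_line(gray_morph_line(x, length, angle, "erode"), length, angle,
                  "dilate")
}

component_elongation <- function(idx, h) {
  ri <- ((idx - 1L) %% h) + 1L
  ci <- ((idx - 1L) %/% h) + 1L
  if (length(idx) < 3) return(1)
  cv <- stats::cov(cbind(ri, ci))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[1], 1e-9) / max(ev[2], 1e-9))
}

# Bounding-box diagonal: crossings of several hairs merge into one component
# whose covariance elongation is near 1, but the network still spans far
# more than any compact artifact (follicle, speck) does.
component_diag <- function(idx, h) {
  ri <- ((idx - 1L) %% h) + 1L
  ci <- ((idx - 1L) %/% h) + 1L
  sqrt((diff(range(ri)) + 1)^2 + (diff(range(ci)) + 1)^2)
}

# Directional nearest-known-value fill with inverse-distance weighting: each
# unknown pixel receives the last known value seen from the four axis
# directions, weighted by 1/distance, so thin removed strands interpolate
# smoothly across their width instead of streaking along their length.
directional_fill <- function(v, known) {
  h <- nrow(v)
  w <- ncol(v)
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  pass <- function(ord_rows, rev_order) {
    n <- if (ord_rows) h else w
    sel <- if (rev_order) n:1 else 1:n
    prev_v <- NULL
    prev_d <- NULL
    for (i in sel) {
      if (ord_rows) {
        vi <- v[i, ]
        ki <- known[i, ]
      } else {
        vi <- v[, i]
        ki <- known[, i]
      }
      di <- ifelse(ki, 0, Inf)
      if (!is.null(prev_v)) {
        closer <- !ki & (prev_d + 1 < di)
        vi[closer] <- prev_v[closer]
        di[closer] <- prev_d[closer] + 1
      }
      wgt <- ifelse(is.finite(di) & di > 0, 1 / di, 0)
      if (ord_rows) {
        num[i, ] <<- num[i, ] + wgt * vi
        den[i, ] <<- den[i, ] + wgt
      } else {
        num[, i] <<- num[, i] + wgt * vi
        den[, i] <<- den[, i] + wgt
      }
      prev_v <- vi
      prev_d <- di
    }
  }
  pass(TRUE, FALSE)
  pass(TRUE, TRUE)
  pass(FALSE, FALSE)
  pass(FALSE, TRUE)
  filled <- v
  reach <- !known & den > 0
  filled[reach] <- num[reach] / den[reach]
  # isolated unknowns with no known pixel on any axis: global fallback
  filled[!known & den == 0] <- stats::median(v[known])
  filled
}

#' Detect and remove hairs and ruler marks
#'
#' Dual-polarity generalization of morphological hair removal: grayscale
#' closing (dark hairs) and opening (light hairs) with linear structuring
#' elements at several orientations; pixels where the filtered-original
#' difference exceeds a threshold become candidates, thin elongated
#' components are kept as hair/ruler, and the removed pixels are filled by
#' neighbourhood-interpolation inpainting followed by light diffusion
#' smoothing.
#'
#' @param image A [derm_image()]; detection is restricted to its valid
#'   mask.
#' @param se_length Structuring-element length in px (scale to resolution).
#' @param angles Structuring-element orientations in degrees.
#' @param diff_threshold Intensity-difference threshold (8-bit units).
#' @param elongation_min Minimal major/minor axis ratio of kept components;
#'   components whose bounding-box diagonal exceeds `2 * se_length` are kept
#'   regardless (crossed hairs merge into networks with near-isotropic
#'   covariance). Compact blobs such as keratotic follicles fail both
#'   criteria.
#' @param min_area Minimal component area in px.
#' @return List: `mask` (logical hair-and-ruler mask) and `image` (the
#'   inpainted [derm_image()]). A hairless image returns an empty mask and
#'   the input image unchanged.
#' @export
remove_hairs <- function(image, se_length = 15L,
                         angles = c(0, 45, 90, 135), diff_threshold = 10,
                         elongation_min = 4, min_area = 40L) {
  stopifnot(inherits(image, "derm_image"))
  g <- derm_gray(image$rgb)
  # neutralize pixels outside the valid region before filtering: the dark
  # frame would otherwise respond to the line elements itself and bridge
  # every nearby candidate into one giant component
  if (!all(image$valid_mask)) {
    g[!image$valid_mask] <- stats::median(g[image$valid_mask])
  }
  dark <- matrix(-Inf, nrow(g), ncol(g))
  light <- matrix(-Inf, nrow(g), ncol(g))
  for (a in angles) {
    dark <- pmax(dark, line_closing(g, se_length, a) - g)
    light <- pmax(light, g - line_opening(g, se_length, a))
  }
  resp <- pmax(dark, light)
  cand <- resp > diff_threshold & image$valid_mask
  mask <- matrix(FALSE, nrow(g), ncol(g))
  if (any(cand)) {
    lab <- EBImage::bwlabel(cand)
    tab <- tabulate(lab[lab > 0])
    keep_ids <- which(tab >= min_area)
    h <- nrow(g)
    for (id in keep_ids) {
      idx <- which(lab == id)
      # two-threshold validation: a component must be thin/elongated AND
      # show clear mean contrast (true hairs are far above the pixel
      # threshold; chains of faint texture blobs are not)
      if (mean(resp[idx]) < 2 * diff_threshold) next
      if (component_elongation(idx, h) >= elongation_min ||
          component_diag(idx, h) >= 2 * se_length) mask[idx] <- TRUE
    }
    if (any(mask)) {
      mask <- EBImage::dilate(mask, EBImage::makeBrush(5, "disc")) > 0
      mask <- mask & image$valid_mask
    }
  }
  if (!any(mask)) {
    return(list(mask = mask, image = image))
  }
  out <- image$rgb
  # frame/background pixels must not seed the fill: they are dark and would
  # bleed into any removed strand that runs near the frame
  known <- !mask & image$valid_mask
  k3 <- matrix(1 / 9, 3, 3)
  for (ch in 1:3) {
    v <- directional_fill(out[, , ch], known)
    for (it in 1:10) {                # diffusion smoothing of the fill
      sm <- EBImage::filter2(v, k3)
      v[mask] <- sm[mask]
    }
    out[, , ch] <- clip8(v)
  }
  list(mask = mask,
       image = derm_image(out, image$valid_mask, image$patient_id,
                          image$lesion_id))
}

#' Decompose a dermatoscopy image into R, G, B, H, S, V channels
#'
#' Standard RGB to HSV conversion; hue is scaled circularly to \[0, 255\],
#' saturation and value linearly to \[0, 255\].
#'
#' @param image A [derm_image()] or (H, W, 3) array.
#' @return Named list of six numeric matrices (`R`, `G`, `B`, `H`, `S`,
#'   `V`), each the input's spatial shape.
#' @export
decompose_channels <- function(image) {
  rgb <- if (inherits(image, "derm_image")) image$rgb else image
  d <- dim(rgb)
  m <- rbind(as.numeric(rgb[, , 1]), as.numeric(rgb[, , 2]),
             as.numeric(rgb[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(R = rgb[, , 1], G = rgb[, , 2], B = rgb[, , 3],
       H = matrix(hsv[1, ] * 255, d[1], d[2]),
       S = matrix(hsv[2, ] * 255, d[1], d[2]),
       V = matrix(hsv[3, ] * 255, d[1], d[2]))
}

#' Handcrafted dermatoscopy features
#'
#' The texture family set (histogram, GLCM, LBP, scattering) computed per
#' channel (R, G, B, H, S, V) restricted to the valid-region mask.
#'
#' @param image A [derm_image()] (its `valid_mask` is used) or a channel
#'   list from [decompose_channels()] plus an explicit `valid_mask`.
#' @param valid_mask Optional logical mask overriding the image's.
#' @param ... Texture options (`glcm_levels`, `lbp_radius`, `scat_J`,
#'   `scat_L`).
#' @return Named feature vector `derm.<channel>.<family>.<stat>`.
#' @export
dermoscopy_handcrafted_features <- function(image, valid_mask = NULL, ...) {
  if (inherits(image, "derm_image")) {
    channels <- decompose_channels(image)
    valid_mask <- valid_mask %||% image$valid_mask
  } else {
    channels <- image
    if (is.null(valid_mask)) stopf("valid_mask required with a channel list")
  }
  if (!any(valid_mask)) stopf("valid mask is empty")
  out <- numeric(0)
  for (ch in names(channels)) {
    tf <- texture_features(channels[[ch]], valid_mask, ...)
    fam <- sub("\\..*$", "", names(tf))
    st <- sub("^[^.]*\\.", "", names(tf))
    out <- c(out, stats::setNames(tf, paste("derm", ch, fam, st, sep = ".")))
  }
  out
}
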