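# Handcrafted HFUS descriptors computed from a scan and its layer masks.
# Feature names follow the scheme  hfus.<family>.<region>.<stat>,  e.g.
# hfus.glcm.sleb.contrast; SLEB-dependent features are NA when the lesion
# has no SLEB.

#' Per-column thickness profile of a layer mask
#'
#' For each image column that intersects the mask, the number of mask pixels
#' in that column; columns without mask pixels are excluded.
#'
#' @param mask Logical matrix.
#' @return Numeric vector of per-column thicknesses (px); `NULL` for an
#'   empty mask (missing-value result).
#' @export
thickness_profile <- function(mask) {
  th <- colSums(mask)
  th <- th[th > 0]
  if (length(th) == 0) return(NULL)
  as.numeric(th)
}

# Perimeter = number of (mask pixel, background 4-neighbour) incidences,
# with out-of-image counting as background: a solid n x n square has
# perimeter 4n, a single pixel 4.
mask_perimeter <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  sum(core & !pad[1:h, 2:(w + 1L)]) +
    sum(core & !pad[3:(h + 2L), 2:(w + 1L)]) +
    sum(core & !pad[2:(h + 1L), 1:w]) +
    sum(core & !pad[2:(h + 1L), 3:(w + 2L)])
}

# Lower boundary depth (row index of the deepest mask pixel) per column.
lower_boundary <- function(mask) {
  cols <- which(colSums(mask) > 0)
  vapply(cols, function(j) max(which(mask[, j])), 0)
}

thickness_stats <- function(mask, prefix) {
  nm <- paste0(prefix, c("thickness_mean", "thickness_sd", "thickness_min",
                         "thickness_q1", "thickness_median", "thickness_q3"))
  th <- thickness_profile(mask)
  if (is.null(th)) return(stats::setNames(rep(NA_real_, 6), nm))
  q <- q13(th)
  stats::setNames(c(mean(th), stats::sd(th), min(th), q[1], q[2], q[3]), nm)
}

#' Morphological layer descriptors
#'
#' Thickness statistics (mean, sd, min, quartiles), perimeter-to-area ratio
#' and boundary-roughness measures for the entry echo and the SLEB, plus
#' depth descriptors of the SLEB lower boundary. The perimeter convention
#' counts background-facing pixel edges with 4-connectivity (a solid n x n
#' square yields 4n / n^2).
#'
#' @param masks A [layer_mask_set()] with a non-empty entry echo.
#' @param pixel_size_mm Optional physical pixel size; when given, thickness
#'   and depth statistics are duplicated on the mm scale (`_mm` suffix).
#' @return Named feature vector (prefix `hfus.morph.`); SLEB entries are NA
#'   when the SLEB mask is empty.
#' @export
morphological_features <- function(masks, pixel_size_mm = NULL) {
  if (!any(masks$entry_echo)) stopf("entry-echo mask is empty")
  out <- c(thickness_stats(masks$entry_echo, "hfus.morph.entry_echo."),
           thickness_stats(masks$sleb, "hfus.morph.sleb."))
  layer_extras <- function(mask, region) {
    nm <- paste0("hfus.morph.", region,
                 c(".perimeter_area", ".boundary_roughness",
                   ".boundary_length_ratio"))
    if (!any(mask)) return(stats::setNames(rep(NA_real_, 3), nm))
    lb <- lower_boundary(mask)
    per <- mask_perimeter(mask)
    stats::setNames(
      c(per / sum(mask),
        stats::sd(lb),
        per / (2 * length(lb))),
      nm)
  }
  out <- c(out, layer_extras(masks$entry_echo, "entry_echo"),
           layer_extras(masks$sleb, "sleb"))
  depth <- c(hfus.morph.sleb.depth_max = NA_real_,
             hfus.morph.sleb.depth_mean = NA_real_)
  if (any(masks$sleb)) {
    lb <- lower_boundary(masks$sleb)
    depth[] <- c(max(lb), mean(lb))
  }
  out <- c(out, depth)
  if (!is.null(pixel_size_mm)) {
    scaled <- grep("thickness|depth|roughness", names(out), value = TRUE)
    mm <- out[scaled] * pixel_size_mm
    names(mm) <- paste0(scaled, "_mm")
    out <- c(out, mm)
  }
  out
}

#' Echogenicity band definition
#'
#' Cut points splitting the 8-bit intensity range into low (LEP), medium
#' (MEP) and high (HEP) echogenic bands: LEP < `low`, `low` <= MEP < `high`,
#' HEP >= `high`.
#'
#' @param low,high Cut points with `0 <= low < high <= 255`.
#' @return An object of class `echogenicity_bands`.
#' @export
echogenicity_bands <- function(low = 30, high = 150) {
  if (!(low >= 0 && low < high && high <= 255)) {
    stopf("need 0 <= low < high <= 255")
  }
  structure(list(low = low, high = high), class = "echogenicity_bands")
}

#' Echogenicity features per layer
#'
#' Fractions of low/medium/high echogenic pixels (LEP/MEP/HEP) and the mean
#' intensity, per region; the three ratios partition to 1 exactly. SLEB
#' values are additionally referenced to the dermis band (each SLEB value
#' divided by the matching dermis value, suffix `_rel`).
#'
#' @param scan An [hfus_scan()] (or plain intensity matrix).
#' @param masks A [layer_mask_set()].
#' @param bands An [echogenicity_bands()].
#' @return Named feature vector (prefix `hfus.echo.`). A zero dermis
#'   denominator yields NA with a warning.
#' @export
echogenicity_features <- function(scan, masks, bands = echogenicity_bands()) {
  px <- if (inherits(scan, "hfus_scan")) scan$pixels else scan
  band_stats <- function(mask) {
    v <- px[mask]
    if (length(v) == 0) return(rep(NA_real_, 4))
    lep <- mean(v < bands$low)
    mep <- mean(v >= bands$low & v < bands$high)
    # complement, not a third division: the partition sums to 1 exactly
    c(lep, mep, 1 - (lep + mep), mean(v))
  }
  stat_names <- c("lep", "mep", "hep", "mean")
  out <- numeric(0)
  vals <- list()
  for (region in c("entry_echo", "sleb", "dermis_reference")) {
    s <- band_stats(masks[[region]])
    vals[[region]] <- s
    rn <- if (region == "dermis_reference") "dermis" else region
    out <- c(out, stats::setNames(s, paste0("hfus.echo.", rn, ".",
                                            stat_names)))
  }
  rel <- stats::setNames(rep(NA_real_, 4),
                         paste0("hfus.echo.sleb.", stat_names, "_rel"))
  if (any(masks$sleb)) {
    if (!any(masks$dermis_reference)) {
      stopf("dermis reference mask required when SLEB is present")
    }
    den <- vals$dermis_reference
    bad <- den == 0
    if (any(bad)) {
      warnf("zero dermis denominator for %s; ratio set to NA",
            paste(stat_names[bad], collapse = ", "))
    }
    rel[!bad] <- vals$sleb[!bad] / den[!bad]
  }
  c(out, rel)
}

#' Texture features of the combined entry echo and SLEB region
#'
#' Computes the full texture family set on the union mask
#' `entry_echo | sleb`; with an empty SLEB this equals the entry-echo-only
#' features.
#'
#' @param scan An [hfus_scan()] (or plain matrix).
#' @param masks A [layer_mask_set()] with non-empty entry echo.
#' @param ... Passed to the texture family functions (`glcm_levels`,
#'   `lbp_radius`, `scat_J`, `scat_L`).
#' @return Named feature vector (prefix `hfus.<family>.combined.`).
#' @export
combined_layer_features <- function(scan, masks, ...) {
  if (!any(masks$entry_echo)) stopf("entry-echo mask is empty")
  px <- if (inherits(scan, "hfus_scan")) scan$pixels else scan
  tf <- texture_features(px, masks$entry_echo | masks$sleb, ...)
  prefix_region(tf, "hfus", "combined")
}

# "<family>.<stat>" -> "<modality>.<family>.<region>.<stat>"
prefix_region <- function(feats, modality, region) {
  fam <- sub("\\..*$", "", names(feats))
  st <- sub("^[^.]*\\.", "", names(feats))
  stats::setNames(feats, paste(modality, fam, region, st, sep = "."))
}

#' All handcrafted HFUS features for one lesion
#'
#' Bundles morphology, echogenicity and per-region texture (histogram, GLCM,
#' LBP, scattering) for the entry echo, the SLEB and the combined
#' entry echo + SLEB region.
#'
#' @param scan An [hfus_scan()].
#' @param masks A [layer_mask_set()].
#' @param bands An [echogenicity_bands()].
#' @param ... Texture options passed down ([combined_layer_features()]).
#' @return Named feature vector; names follow
#'   `hfus.<family>.<region>.<stat>`.
#' @export
hfus_features <- function(scan, masks, bands = echogenicity_bands(), ...) {
  px <- if (inherits(scan, "hfus_scan")) scan$pixels else scan
  psz <- if (inherits(scan, "hfus_scan")) scan$pixel_size_mm else NULL
  c(morphological_features(masks, pixel_size_mm = psz),
    echogenicity_features(scan, masks, bands),
    prefix_region(texture_features(px, masks$entry_echo, ...), "hfus",
                  "entry_echo"),
    prefix_region(texture_features(px, masks$sleb, ...), "hfus", "sleb"),
    combined_layer_features(scan, masks, ...))
}
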