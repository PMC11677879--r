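#' HFUS B-scan container
#'
#' Wraps one 8-bit grayscale high-frequency ultrasound B-scan. Rows are depth
#' (axial), columns are lateral position, as produced by a linear-array skin
#' probe.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\]; rows = depth,
#'   columns = lateral position. At least 64 x 64.
#' @param patient_id,lesion_id Identifiers carried through the pipeline.
#' @param pixel_size_mm Optional physical pixel size (mm/px); when present,
#'   thickness descriptors are additionally reported in mm.
#' @return An object of class `hfus_scan`.
#' @export
hfus_scan <- function(pixels, patient_id = NA_character_,
                      lesion_id = NA_character_, pixel_size_mm = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    stopf("HFUS scan must be at least 64 x 64 px, got %d x %d",
          nrow(pixels), ncol(pixels))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stopf("HFUS intensities must be finite and in [0, 255]")
  }
  structure(
    list(pixels = pixels, patient_id = as.character(patient_id),
         lesion_id = as.character(lesion_id), pixel_size_mm = pixel_size_mm),
    class = "hfus_scan"
  )
}

#' @export
print.hfus_scan <- function(x, ...) {
  cat(sprintf("<hfus_scan %s/%s: %d x %d px%s>\n", x$patient_id, x$lesion_id,
              nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$pixel_size_mm)) "" else
                sprintf(", %.4g mm/px", x$pixel_size_mm)))
  invisible(x)
}

#' Skin-layer mask set
#'
#' Pairwise-disjoint binary masks for the entry echo, the subepidermal low
#' echogenic band (SLEB; may be empty) and the dermis reference band, all
#' aligned to one scan.
#'
#' @param entry_echo,sleb,dermis_reference Logical matrices of one common
#'   shape. `sleb` and `dermis_reference` default to empty masks.
#' @return An object of class `layer_mask_set`.
#' @export
layer_mask_set <- function(entry_echo, sleb = NULL, dermis_reference = NULL) {
  entry_echo <- as.matrix(entry_echo) > 0
  empty <- array(FALSE, dim(entry_echo))
  sleb <- if (is.null(sleb)) empty else as.matrix(sleb) > 0
  dermis_reference <- if (is.null(dermis_reference)) empty else
    as.matrix(dermis_reference) > 0
  dims <- list(dim(entry_echo), dim(sleb), dim(dermis_reference))
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stopf("all layer masks must share one shape")
  }
  if (any(entry_echo & sleb) || any(entry_echo & dermis_reference) ||
      any(sleb & dermis_reference)) {
    stopf("layer masks must be pairwise disjoint")
  }
  structure(list(entry_echo = entry_echo, sleb = sleb,
                 dermis_reference = dermis_reference),
            class = "layer_mask_set")
}

#' @export
print.layer_mask_set <- function(x, ...) {
  cat(sprintf(
    "<layer_mask_set %d x %d: entry echo %d px, SLEB %d px, dermis ref %d px>\n",
    nrow(x$entry_echo), ncol(x$entry_echo), sum(x$entry_echo), sum(x$sleb),
    sum(x$dermis_reference)))
  invisible(x)
}

#' Dermatoscopy image container
#'
#' @param rgb Numeric (H, W, 3) array with 8-bit channel values in \[0, 255\].
#' @param valid_mask Optional logical matrix marking pixels that carry skin
#'   information (frame, blurred background and measurement marks excluded).
#'   Defaults to the full image.
#' @param patient_id,lesion_id Identifiers.
#' @return An object of class `derm_image`.
#' @export
derm_image <- function(rgb, valid_mask = NULL, patient_id = NA_character_,
                       lesion_id = NA_character_) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stopf("dermatoscopy image must be an (H, W, 3) array")
  }
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255) {
    stopf("channel values must be finite and in [0, 255]")
  }
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, dim(rgb)[1], dim(rgb)[2])
  if (!identical(dim(valid_mask), dim(rgb)[1:2])) {
    stopf("valid_mask shape must match the image")
  }
  structure(list(rgb = rgb, valid_mask = valid_mask > 0,
                 patient_id = as.character(patient_id),
                 lesion_id = as.character(lesion_id)),
            class = "derm_image")
}

#' @export
print.derm_image <- function(x, ...) {
  cat(sprintf("<derm_image %s/%s: %d x %d px, %.1f%% valid>\n", x$patient_id,
              x$lesion_id, dim(x$rgb)[1], dim(x$rgb)[2],
              100 * mean(x$valid_mask)))
  invisible(x)
}
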