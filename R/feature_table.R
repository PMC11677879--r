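# Assembly of per-lesion feature vectors into cohort-level feature tables
# (rows = lesions, columns = named features; keys patient_id, lesion_id,
# stage). Missing values (e.g. SLEB-absent lesions) stay NA; imputation
# happens only inside the classifier's training folds.

bind_feature_rows <- function(keys, feats) {
  nm <- names(feats[[1]])
  mat <- do.call(rbind, lapply(feats, function(f) f[nm]))
  colnames(mat) <- nm
  cbind(keys, as.data.frame(mat, check.names = FALSE))
}

#' HFUS feature table for a cohort
#'
#' Computes the handcrafted HFUS descriptor set per lesion, from either the
#' ground-truth masks or masks predicted by a trained segmentation model.
#'
#' @param cohort An `ak_cohort` with the HFUS modality.
#' @param masks `"truth"` for ground-truth masks or `"model"` to segment
#'   each scan with `model`.
#' @param model A trained `seg_model` (required when `masks = "model"`).
#' @param bands An [echogenicity_bands()].
#' @param ... Texture options passed to [hfus_features()].
#' @return Feature table data.frame.
#' @export
hfus_feature_table <- function(cohort, masks = c("truth", "model"),
                               model = NULL, bands = echogenicity_bands(),
                               ...) {
  stopifnot(inherits(cohort, "ak_cohort"))
  masks <- match.arg(masks)
  if (masks == "model" && is.null(model)) {
    stopf("masks = \"model\" requires a trained segmentation model")
  }
  feats <- lapply(cohort$lesions, function(les) {
    if (is.null(les$hfus)) stopf("lesion %s has no HFUS scan", les$lesion_id)
    ms <- if (masks == "truth") les$hfus$masks else
      segment_layers(model, les$hfus$scan, quiet = TRUE)
    hfus_features(les$hfus$scan, ms, bands, ...)
  })
  keys <- data.frame(patient_id = cohort_patients(cohort),
                     lesion_id = vapply(cohort$lesions, `[[`, "", "lesion_id"),
                     stage = cohort_stages(cohort))
  bind_feature_rows(keys, feats)
}

#' Dermatoscopy feature table for a cohort
#'
#' Optionally preprocesses each image (frame/background removal, hair and
#' ruler removal with inpainting), then computes per-channel handcrafted
#' texture features and/or CNN extractor features.
#'
#' @param cohort An `ak_cohort` with the dermatoscopy modality.
#' @param extractor A [feature_extractor()] or `NULL` to skip CNN features.
#' @param handcrafted Compute the handcrafted channel features?
#' @param preprocess Run frame and hair removal first?
#' @param ... Texture options passed to
#'   [dermoscopy_handcrafted_features()].
#' @return Feature table data.frame.
#' @export
derm_feature_table <- function(cohort, extractor = NULL, handcrafted = TRUE,
                               preprocess = TRUE, ...) {
  stopifnot(inherits(cohort, "ak_cohort"))
  if (!handcrafted && is.null(extractor)) {
    stopf("nothing to extract: enable handcrafted features or supply an extractor")
  }
  feats <- lapply(cohort$lesions, function(les) {
    if (is.null(les$derm)) stopf("lesion %s has no dermatoscopy image",
                                 les$lesion_id)
    img <- les$derm$image
    if (preprocess) {
      img$valid_mask <- remove_frame_and_background(img)
      img <- remove_hairs(img)$image
    }
    out <- numeric(0)
    if (handcrafted) {
      out <- c(out, dermoscopy_handcrafted_features(img, ...))
    }
    if (!is.null(extractor)) out <- c(out, cnn_features(img, extractor))
    out
  })
  keys <- data.frame(patient_id = cohort_patients(cohort),
                     lesion_id = vapply(cohort$lesions, `[[`, "", "lesion_id"),
                     stage = cohort_stages(cohort))
  bind_feature_rows(keys, feats)
}

#' Merge feature tables on lesion keys
#'
#' @param ... Feature tables sharing `patient_id`, `lesion_id`, `stage`.
#' @return Merged feature table.
#' @export
merge_feature_tables <- function(...) {
  tables <- list(...)
  Reduce(function(a, b) merge(a, b, by = c("patient_id", "lesion_id",
                                           "stage"), sort = FALSE), tables)
}

#' Write / read a feature table as CSV
#'
#' Feature tags (modality, family, region) are encoded in the column-name
#' scheme `modality.family.region.stat`, so the CSV round-trips losslessly.
#'
#' @param table Feature table.
#' @param path CSV path.
#' @return `read_feature_table` returns the table; `write_feature_table`
#'   the path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
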