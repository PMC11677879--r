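test_that("lateral cropping honours the width contract", {
  big <- hfus_scan(matrix(round(runif(224 * 1024, 0, 255)), 224, 1024))
  cr <- crop_scan(big, 512L)
  expect_identical(dim(cr$pixels), c(224L, 512L))
  expect_identical(cr$pixels, big$pixels[, 257:768])   # centered window

  same <- crop_scan(hfus_scan(matrix(128, 224, 512)), 512L)
  expect_identical(dim(same$pixels), c(224L, 512L))

  expect_error(crop_scan(hfus_scan(matrix(0, 100, 100)), 512L), "exceeds")

  off <- crop_scan(big, 512L, center = 10)   # window clamped to the left edge
  expect_identical(off$pixels, big$pixels[, 1:512])
})

test_that("dice index matches its closed form and is symmetric", {
  a <- matrix(FALSE, 8, 8)
  a[1:2, 1:2] <- TRUE            # |A| = 4
  b <- matrix(FALSE, 8, 8)
  b[1:2, 1] <- TRUE              # |B| = 2, overlap 2
  expect_equal(dice_index(a, b), 2 * 2 / (4 + 2))
  expect_equal(dice_index(a, b), dice_index(b, a))
  expect_equal(dice_index(a, a), 1)
  disjoint <- matrix(FALSE, 8, 8)
  disjoint[5, 5] <- TRUE
  expect_equal(dice_index(a, disjoint), 0)
  empty <- matrix(FALSE, 8, 8)
  expect_equal(dice_index(empty, empty), 1)   # agreement on absence
  expect_error(dice_index(a, matrix(FALSE, 4, 4)), "shape")
  # dice = 1 iff identical, over random masks
  set.seed(1)
  for (i in 1:20) {
    m1 <- matrix(runif(64) > 0.5, 8, 8)
    m2 <- matrix(runif(64) > 0.5, 8, 8)
    expect_equal(dice_index(m1, m2) == 1, identical(m1, m2))
  }
})

test_that("model construction is seeded, shaped and numerically sane", {
  cfg <- seg_model_config(input_height = 64L, input_width = 64L)
  m1 <- suppressMessages(build_model(cfg))
  m2 <- suppressMessages(build_model(cfg))
  expect_identical(m1$params, m2$params)

  x <- array(0, dim = c(64, 64, 1))
  fw <- akstage:::seg_forward(m1$params, x, cfg$dilations, want_cache = FALSE)
  expect_identical(dim(fw$logits), c(64L, 64L, 3L))
  expect_true(all(is.finite(fw$logits)))

  expect_error(build_model(seg_model_config(input_height = 66L,
                                            input_width = 64L)),
               "divisible")
  expect_error(seg_model_config(n_classes = 5L), "3 or 4")
})

test_that("training on one phantom overfits it (capacity sanity)", {
  p <- phantom_params(hfus_height = 64L, hfus_width = 128L,
                      dermis_band_depth = 20, sleb_thickness_mean = 12)
  ph <- generate_hfus_phantom(p, 2, seed = 31, force_sleb = TRUE)
  cfg <- seg_model_config(input_height = 64L, input_width = 128L,
                          widths = c(8L, 16L, 32L), epochs = 200L, seed = 1L)
  model <- suppressMessages(build_model(cfg))
  x <- akstage:::scan_to_input(ph$scan)
  y <- akstage:::masks_to_labels(ph$masks)
  # "enough epochs": train in chunks until the single image is memorized
  dice <- 0
  for (chunk in 1:6) {
    model <- akstage:::seg_fit(model, list(x), list(y), seed = chunk + 1L)
    pred <- segment_layers(model, ph$scan, quiet = TRUE)
    dice <- dice_index(pred$entry_echo, ph$masks$entry_echo)
    if (dice > 0.995) break
  }
  expect_gt(dice, 0.99)
})

test_that("patient-grouped folds never split a patient", {
  fo <- akstage:::patient_folds(rep(sprintf("P%02d", 1:8), each = 3), 4L,
                                seed = 3)
  expect_length(fo, 8)
  expect_identical(sort(unique(as.integer(fo))), 1:4)
  expect_error(akstage:::patient_folds(c("A", "A", "A"), 2L), "cannot split")
})

test_that("segmentation output flags degenerate empty predictions", {
  cfg <- seg_model_config(input_height = 64L, input_width = 64L)
  model <- suppressMessages(build_model(cfg))  # untrained: arbitrary output
  scan <- hfus_scan(matrix(0, 64, 64))
  res <- suppressWarnings(segment_layers(model, scan))
  expect_s3_class(res, "layer_mask_set")
  if (!any(res$entry_echo)) {
    expect_true(attr(res, "degenerate"))
    expect_warning(segment_layers(model, scan), "degenerate")
  } else {
    expect_false(attr(res, "degenerate"))
  }
  # masks disjoint and shape-aligned whatever the network says
  expect_identical(dim(res$entry_echo), dim(scan$pixels))
  expect_false(any(res$entry_echo & res$sleb))
})

test_that("dermis reference derives as a band under the deepest layer", {
  entry <- matrix(FALSE, 40, 6)
  entry[3:5, ] <- TRUE
  sleb <- matrix(FALSE, 40, 6)
  sleb[6:10, 1:3] <- TRUE      # SLEB only under half the columns
  ref <- akstage:::derive_dermis_reference(entry, sleb, depth = 4L)
  expect_true(all(ref[11:14, 1:3]))
  expect_true(all(ref[6:9, 4:6]))
  expect_equal(sum(ref), 4 * 6)
})

test_that("cross-validated training cannot run with one patient", {
  co <- generate_cohort(1, c(2, 0, 0), phantom_params(), seed = 1,
                        modalities = "hfus")
  expect_error(train_segmentation(co, 2, seg_model_config(epochs = 1L)),
               "cannot split")
})
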