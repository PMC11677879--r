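test_that("phantom parameters enforce the physical invariants", {
  expect_s3_class(phantom_params(), "phantom_params")
  expect_error(phantom_params(entry_thickness_mean = c(10, 10, -1)),
               "positive")
  expect_error(phantom_params(mean_entry = 300), "\\[0, 255\\]")
  expect_error(phantom_params(entry_thickness_mean = c(16, 12, 8)),
               "stage-3")
  expect_error(phantom_params(mean_sleb = 130), "dermis")
  expect_error(phantom_params(not_a_param = 1), "unknown")
})

test_that("zero-speckle phantom is piecewise constant at the layer means", {
  p <- phantom_params(speckle_background = 0, speckle_entry = 0,
                      speckle_sleb = 0, speckle_dermis = 0)
  ph <- generate_hfus_phantom(p, stage = 2, seed = 7, force_sleb = TRUE)
  px <- ph$scan$pixels
  expect_true(all(px[ph$masks$entry_echo] == p$mean_entry))
  expect_true(all(px[ph$masks$sleb] == p$mean_sleb[2]))
  expect_true(all(px[ph$masks$dermis_reference] == p$mean_dermis))
})

test_that("same parameters and seed give bit-identical phantoms", {
  p <- phantom_params()
  a <- generate_hfus_phantom(p, 3, seed = 123)
  b <- generate_hfus_phantom(p, 3, seed = 123)
  expect_identical(a$scan$pixels, b$scan$pixels)
  expect_identical(a$masks, b$masks)
  d1 <- generate_dermoscopy_phantom(phantom_params(derm_size = 96L), 1,
                                    seed = 5)
  d2 <- generate_dermoscopy_phantom(phantom_params(derm_size = 96L), 1,
                                    seed = 5)
  expect_identical(d1$image$rgb, d2$image$rgb)
  expect_identical(d1$hair_mask, d2$hair_mask)
})

test_that("generated masks are disjoint and ordered top to bottom", {
  for (seed in 1:5) {
    ph <- generate_hfus_phantom(phantom_params(), stage = (seed %% 3) + 1,
                                seed = seed)
    m <- ph$masks
    expect_false(any(m$entry_echo & m$sleb))
    expect_false(any(m$entry_echo & m$dermis_reference))
    expect_false(any(m$sleb & m$dermis_reference))
    for (j in seq_len(ncol(m$entry_echo))) {
      e <- which(m$entry_echo[, j])
      s <- which(m$sleb[, j])
      d <- which(m$dermis_reference[, j])
      if (length(s)) expect_true(max(e) < min(s))
      if (length(d)) expect_true(max(c(e, s)) < min(d))
    }
  }
})

test_that("entry-echo thickness draws exceeding the image error out", {
  p <- phantom_params(hfus_height = 128L, entry_thickness_mean = c(50, 60, 500),
                      entry_thickness_sd = c(1, 1, 1))
  expect_error(generate_hfus_phantom(p, 3, seed = 1), "100 attempts")
})

test_that("median entry-echo thickness is monotone non-decreasing in stage", {
  p <- phantom_params()
  med <- vapply(1:3, function(st) {
    th <- vapply(1:200, function(i) {
      ph <- generate_hfus_phantom(p, st, seed = 1000 * st + i)
      stats::median(thickness_profile(ph$masks$entry_echo))
    }, 0)
    stats::median(th)
  }, 0)
  expect_true(med[1] <= med[2] && med[2] <= med[3])
  expect_lt(med[1], med[3])   # the trend is strict across the extremes
})

test_that("artifact-free dermatoscopy phantom equals its clean image", {
  ph <- generate_dermoscopy_phantom(phantom_params(derm_size = 96L), 2,
                                    seed = 3, hair_count = 0L, frame = FALSE,
                                    ruler = FALSE)
  expect_identical(ph$image$rgb, ph$clean)
  expect_false(any(ph$hair_mask))
  expect_false(any(ph$frame_mask))
})

test_that("hair and frame ground-truth masks are non-empty and disjoint", {
  ph <- generate_dermoscopy_phantom(phantom_params(derm_size = 128L), 2,
                                    seed = 3, hair_count = 12L)
  expect_gt(sum(ph$hair_mask), 0)
  expect_gt(sum(ph$frame_mask), 0)
  expect_false(any(ph$hair_mask & ph$frame_mask))
  expect_error(generate_dermoscopy_phantom(phantom_params(derm_size = 96L),
                                           1, seed = 1, hair_count = -1),
               "hair_count")
})

test_that("stage-3 lesions are brighter than stage-1 (keratotic surface)", {
  p <- phantom_params(derm_size = 96L)
  mean_b <- vapply(c(1, 3), function(st) {
    ph <- generate_dermoscopy_phantom(p, st, seed = 11, hair_count = 0L,
                                      frame = FALSE, ruler = FALSE)
    s <- dim(ph$clean)[1]
    xx <- matrix(seq_len(s), s, s)
    yy <- matrix(seq_len(s), s, s, byrow = TRUE)
    lesion <- sqrt((xx - s / 2)^2 + (yy - s / 2)^2) < 0.3 * s
    mean(ph$clean[cbind(rep(which(lesion), 3),
                        rep(1:3, each = sum(lesion)))])
  }, 0)
  expect_gt(mean_b[2], mean_b[1])
})

test_that("cohort generation distributes lesions and respects counts", {
  co <- generate_cohort(3, c(3, 0, 0), seed = 5, modalities = "hfus")
  expect_length(co$lesions, 3)
  expect_identical(sort(unique(cohort_patients(co))), c("P001", "P002", "P003"))
  expect_true(all(cohort_stages(co) == 1))

  co2 <- generate_cohort(1, c(1, 1, 1), seed = 2, modalities = "hfus")
  expect_length(co2$lesions, 3)
  expect_identical(unique(cohort_patients(co2)), "P001")
  expect_setequal(cohort_stages(co2), 1:3)

  co3 <- generate_cohort(5, c(6, 3, 2), seed = 9, modalities = "hfus")
  expect_identical(as.integer(table(cohort_stages(co3))), c(6L, 3L, 2L))
  expect_error(generate_cohort(10, c(2, 2, 2)), ">=")
  expect_error(generate_cohort(2, c(-1, 3, 3)), "non-negative")
})

test_that("the default class counts log their one-lesion discrepancy", {
  expect_message(
    co <- generate_cohort(54, c(92L, 42L, 27L),
                          phantom_params(hfus_height = 64L, hfus_width = 64L),
                          seed = 1, modalities = character(0)),
    "161")
  expect_length(co$lesions, 161)
})

test_that("cohorts are byte-identical under a fixed seed", {
  a <- generate_cohort(4, c(4, 2, 2), seed = 33, modalities = "hfus")
  b <- generate_cohort(4, c(4, 2, 2), seed = 33, modalities = "hfus")
  expect_identical(a, b)
})
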