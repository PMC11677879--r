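test_that("thickness profile counts per-column mask pixels", {
  band <- matrix(FALSE, 30, 10)
  band[5:14, ] <- TRUE
  expect_identical(thickness_profile(band), rep(10, 10))

  half <- matrix(FALSE, 30, 10)
  half[1:5, 1:5] <- TRUE
  half[1:15, 6:10] <- TRUE
  th <- thickness_profile(half)
  expect_equal(stats::median(th), 10)
  expect_equal(stats::quantile(th, 0.75, names = FALSE), 15)

  single <- matrix(FALSE, 30, 10)
  single[7, 3] <- TRUE
  expect_identical(thickness_profile(single), 1)

  expect_null(thickness_profile(matrix(FALSE, 5, 5)))
})

test_that("perimeter convention matches edge-counting enumeration", {
  for (n in c(1, 2, 3, 5)) {
    sq <- matrix(FALSE, 10, 10)
    sq[3:(2 + n), 3:(2 + n)] <- TRUE
    expect_equal(akstage:::mask_perimeter(sq), 4 * n)   # 4n exposed edges
    expect_equal(akstage:::mask_perimeter(sq), perimeter_oracle(sq))
  }
  set.seed(8)
  for (i in 1:25) {
    m <- matrix(runif(100) > 0.6, 10, 10)
    expect_equal(akstage:::mask_perimeter(m), perimeter_oracle(m))
  }
})

test_that("morphological features expose the documented statistics", {
  entry <- matrix(FALSE, 60, 20)
  entry[4:9, ] <- TRUE          # uniform 6 px band
  sleb <- matrix(FALSE, 60, 20)
  sleb[10:19, ] <- TRUE         # uniform 10 px band
  mf <- morphological_features(layer_mask_set(entry, sleb))
  expect_equal(unname(mf["hfus.morph.entry_echo.thickness_mean"]), 6)
  expect_equal(unname(mf["hfus.morph.entry_echo.thickness_sd"]), 0)
  expect_equal(unname(mf["hfus.morph.sleb.thickness_q3"]), 10)
  expect_equal(unname(mf["hfus.morph.sleb.depth_max"]), 19)
  expect_equal(unname(mf["hfus.morph.entry_echo.perimeter_area"]),
               perimeter_oracle(entry) / sum(entry))
  # SLEB-absent lesions carry explicit missing values
  mf2 <- morphological_features(layer_mask_set(entry))
  expect_true(all(is.na(mf2[grep("sleb", names(mf2))])))
  expect_error(morphological_features(layer_mask_set(matrix(FALSE, 4, 4))),
               "empty")
})

test_that("echogenicity ratios partition to one and reference the dermis", {
  set.seed(3)
  px <- matrix(round(runif(64 * 64, 0, 255)), 64, 64)
  entry <- matrix(FALSE, 64, 64)
  entry[1:5, ] <- TRUE
  sleb <- matrix(FALSE, 64, 64)
  sleb[10:20, ] <- TRUE
  dref <- matrix(FALSE, 64, 64)
  dref[30:50, ] <- TRUE
  ef <- echogenicity_features(px, layer_mask_set(entry, sleb, dref))
  for (region in c("entry_echo", "sleb", "dermis")) {
    expect_equal(unname(ef[paste0("hfus.echo.", region, ".lep")] +
                        ef[paste0("hfus.echo.", region, ".mep")] +
                        ef[paste0("hfus.echo.", region, ".hep")]), 1)
  }
  expect_equal(unname(ef["hfus.echo.sleb.mean_rel"]),
               unname(ef["hfus.echo.sleb.mean"] / ef["hfus.echo.dermis.mean"]))

  # hand-counted band ratios: 3 px low, 5 px mid, 2 px high
  vals <- c(rep(10, 3), rep(80, 5), rep(200, 2))
  px2 <- matrix(0, 64, 64)
  px2[1, 1:10] <- vals
  m <- matrix(FALSE, 64, 64)
  m[1, 1:10] <- TRUE
  ef2 <- echogenicity_features(px2, layer_mask_set(m))
  expect_equal(unname(ef2["hfus.echo.entry_echo.lep"]), 0.3)
  expect_equal(unname(ef2["hfus.echo.entry_echo.mep"]), 0.5)
  expect_equal(unname(ef2["hfus.echo.entry_echo.hep"]), 0.2)

  # all-zero region is entirely low echogenic
  ef3 <- echogenicity_features(matrix(0, 64, 64), layer_mask_set(m))
  expect_equal(unname(ef3["hfus.echo.entry_echo.lep"]), 1)
  expect_equal(unname(ef3["hfus.echo.entry_echo.hep"]), 0)

  expect_error(echogenicity_bands(150, 30), "low")
})

test_that("SLEB/dermis ratios equal one for identically distributed regions", {
  set.seed(11)
  px <- matrix(round(runif(200 * 100, 40, 160)), 200, 100)  # one distribution
  entry <- matrix(FALSE, 200, 100)
  entry[1:5, ] <- TRUE
  sleb <- matrix(FALSE, 200, 100)
  sleb[21:70, ] <- TRUE       # 5000 px
  dref <- matrix(FALSE, 200, 100)
  dref[101:150, ] <- TRUE     # 5000 px
  ef <- suppressWarnings(
    echogenicity_features(px, layer_mask_set(entry, sleb, dref)))
  expect_equal(unname(ef["hfus.echo.sleb.mean_rel"]), 1, tolerance = 0.02)
  expect_equal(unname(ef["hfus.echo.sleb.mep_rel"]), 1, tolerance = 0.05)
})

test_that("histogram entropy hits its closed-form anchors", {
  m <- matrix(TRUE, 16, 16)
  expect_equal(unname(histogram_features(matrix(7, 16, 16), m)["entropy"]), 0)
  two <- matrix(c(0, 255), 16, 16)
  expect_equal(unname(histogram_features(two, m)["entropy"]), 1)
  expect_equal(unname(histogram_features(matrix(0:255, 16, 16),
                                         m)["entropy"]), 8)
  hf <- histogram_features(two, m)
  expect_equal(unname(hf["mean"]), 127.5)
})

test_that("combined-layer features reduce to entry echo when SLEB is absent", {
  ph <- small_hfus_phantom()
  masks_no_sleb <- layer_mask_set(ph$masks$entry_echo,
                                  dermis_reference = ph$masks$dermis_reference)
  comb <- combined_layer_features(ph$scan, masks_no_sleb)
  entry_only <- akstage:::prefix_region(
    akstage:::texture_features(ph$scan$pixels, ph$masks$entry_echo),
    "hfus", "combined")
  expect_equal(comb, entry_only)
  # disjointness: union area is the sum of areas
  expect_equal(sum(ph$masks$entry_echo | ph$masks$sleb),
               sum(ph$masks$entry_echo) + sum(ph$masks$sleb))
})

test_that("features ignore everything outside the mask (padding invariance)", {
  ph <- small_hfus_phantom()
  px <- ph$scan$pixels
  masks <- ph$masks
  f1 <- suppressWarnings(hfus_features(px, masks))
  px2 <- px
  px2[!(masks$entry_echo | masks$sleb | masks$dermis_reference)] <- 255
  f2 <- suppressWarnings(hfus_features(px2, masks))
  expect_equal(f1, f2)
})

test_that("full HFUS feature vector is complete and consistently named", {
  ph <- small_hfus_phantom()
  f <- suppressWarnings(hfus_features(ph$scan, ph$masks))
  expect_true(all(grepl("^hfus\\.(morph|echo|hist|glcm|lbp|scat)\\.", names(f))))
  expect_false(any(duplicated(names(f))))
  expect_true("hfus.glcm.sleb.contrast" %in% names(f))
  expect_true("hfus.morph.entry_echo.thickness_q3" %in% names(f))
  expect_true(all(is.finite(f) | is.na(f)))
})
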