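test_that("the catalog freezes 240 unique names with the family split", {
  cat240 <- feature_catalog()
  expect_equal(nrow(cat240), 240)
  expect_equal(anyDuplicated(cat240$name), 0)
  counts <- table(cat240$family)
  expect_equal(unname(counts[c("intensity", "basic_morphology", "SER",
                               "haralick", "STAR")]),
               c(9, 4, 16, 4, 207), ignore_attr = TRUE)
  expect_equal(sum(cat240$variant != "raw"), 8 * 23)
  expect_true("Nucleus Radial Mean SER-Edge" %in% cat240$name)
})

test_that("intensity properties match hand computations", {
  img <- matrix(0, 4, 4)
  img[1, 1:4] <- c(2, 4, 6, 8)
  roi <- roi_from_mask(row(img) == 1)
  v <- intensity_properties(roi, img)
  expect_equal(unname(v["Intensity Nucleus Sum"]), 20)
  expect_equal(unname(v["Intensity Nucleus Mean"]), 5)
  expect_equal(unname(v["Intensity Nucleus Median"]), 5)
  expect_equal(unname(v["Intensity Nucleus Max"]), 8)
  expect_equal(unname(v["Intensity Nucleus Min"]), 2)
  expect_equal(unname(v["Intensity Nucleus Contrast"]), 0.6)
  expect_equal(unname(v["Intensity Nucleus SD"]), sqrt(5))
  expect_equal(unname(v["Intensity Nucleus CV"]), 100 * sqrt(5) / 5)
  expect_equal(unname(v["Intensity Nucleus Quantile50"]),
               unname(v["Intensity Nucleus Median"]))

  flat <- matrix(10, 2, 2)
  roi2 <- roi_from_mask(matrix(TRUE, 2, 2))
  v2 <- intensity_properties(roi2, flat)
  expect_equal(unname(v2[c("Intensity Nucleus SD", "Intensity Nucleus CV",
                           "Intensity Nucleus Contrast")]), c(0, 0, 0))
  expect_equal(unname(v2["Intensity Nucleus Sum"]), 40)

  # homogeneity: scaling pixels by k scales first moments, not CV/contrast
  v3 <- intensity_properties(roi, img * 7)
  expect_equal(unname(v3["Intensity Nucleus Mean"]), 35)
  expect_equal(unname(v3["Intensity Nucleus CV"]), unname(v["Intensity Nucleus CV"]))
  expect_equal(unname(v3["Intensity Nucleus Contrast"]),
               unname(v["Intensity Nucleus Contrast"]))
})

test_that("basic morphology matches disc and rectangle oracles", {
  disc <- roi_from_mask(disc_mask(48, 20))
  v <- basic_morphology(disc, pixel_size = 1)
  expect_gte(unname(v["Nucleus Roundness"]), 0.95)
  expect_lte(unname(v["Nucleus Length"] / v["Nucleus Width"]), 1.05)

  rect <- roi_from_mask(row(matrix(0, 60, 60)) <= 10 &
                          col(matrix(0, 60, 60)) <= 40)
  vr <- basic_morphology(rect, pixel_size = 1)
  expect_equal(unname(vr["Nucleus Length"] / vr["Nucleus Width"]), 4,
               tolerance = 0.05)

  m100 <- roi_from_mask(row(matrix(0, 20, 20)) <= 10 &
                          col(matrix(0, 20, 20)) <= 10)
  expect_equal(unname(basic_morphology(m100, 1)["Nucleus Area"]), 100)
  # micrometre scaling enters through the pixel size squared
  expect_equal(unname(basic_morphology(m100, 0.5)["Nucleus Area"]), 25)

  single <- roi_from_mask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  vs <- basic_morphology(single, 0.65)
  expect_equal(unname(vs["Nucleus Width"]), 0.65)
  expect_equal(unname(vs["Nucleus Roundness"]), 1)
})

test_that("SER responses vanish on constant images and detect blobs and ridges", {
  const <- matrix(42, 32, 32)
  bank <- ser_filter_bank(const, 1)
  for (nm in names(bank)) expect_equal(max(abs(bank[[nm]])), 0)

  # isotropic Gaussian blob: at its centre l1 = l2 < 0, so spot dominates
  blob <- 1000 * outer(1:64, 1:64, function(r, c) {
    exp(-((r - 32)^2 + (c - 32)^2) / (2 * 6^2))
  })
  bb <- ser_filter_bank(blob, 1)
  for (nm in c("Ridge", "Valley", "Saddle", "Hole")) {
    expect_gt(bb$Spot[32, 32], bb[[nm]][32, 32])
  }

  # vertical bright line: one large negative eigenvalue, one ~0
  line <- matrix(0, 64, 64); line[, 32] <- 1000
  bl <- ser_filter_bank(line, 1)
  expect_gt(bl$Ridge[32, 32], bl$Spot[32, 32])

  expect_error(ser_filter_bank(blob, 0), "positive")
})

test_that("Haralick features match the hand-built checkerboard GLCM", {
  roi <- roi_from_mask(matrix(TRUE, 2, 2))
  img <- matrix(c(0, 31, 31, 0), 2, 2)
  v <- haralick_features(roi, img)
  expect_equal(unname(v["Nucleus Haralick Homogeneity"]), 1 / (1 + 31^2))
  expect_equal(unname(v["Nucleus Haralick Contrast"]), 31^2)
  expect_equal(unname(v["Nucleus Haralick Correlation"]), -1)
  expect_equal(unname(v["Nucleus Haralick Sum Variance"]), 0)

  expect_equal(unname(haralick_features(roi, matrix(5, 2, 2))),
               c(0, 0, 1, 0))
})

test_that("STAR radial properties match hand computations", {
  # all intensity at the centroid pixel
  m <- disc_mask(21, 6)
  img <- matrix(0, 21, 21); img[11, 11] <- 5
  v <- star_properties(roi_from_mask(m), img)
  expect_equal(unname(v["Radial Mean"]), 0)

  # uniform one-pixel-wide ring of radius 7
  ring <- outer(1:31, 1:31, function(r, c) {
    d <- sqrt((r - 16)^2 + (c - 16)^2); abs(d - 7) < 0.5
  })
  rimg <- matrix(0, 31, 31); rimg[ring] <- 10
  vr <- star_properties(roi_from_mask(ring), rimg)
  expect_equal(unname(vr["Radial Mean"]), 7, tolerance = 0.5 / 7)

  # two pixels at distances 1 and 3 from the weighted centroid
  two <- matrix(FALSE, 5, 7); two[3, c(2, 6)] <- TRUE
  timg <- matrix(0, 5, 7); timg[3, 2] <- 3; timg[3, 6] <- 1
  vt <- star_properties(roi_from_mask(two), timg)
  expect_equal(unname(vt["Radial Mean"]), 1.5)

  # circularly symmetric blob: all angular moments near zero
  big <- disc_mask(41, 15)
  bimg <- 100 * outer(1:41, 1:41, function(r, c) {
    exp(-((r - 21)^2 + (c - 21)^2) / 60)
  })
  vb <- star_properties(roi_from_mask(big), bimg)
  expect_lte(max(vb[sprintf("Symmetry %02d", 1:8)]), 0.05)
  expect_gte(min(vb[sprintf("Threshold Compactness %d%%", c(3:7) * 10)]), 0.9)
})

test_that("feature vectors are complete, finite and translation-invariant", {
  states <- data.frame(phase = "SG2M", dna_content = 3.1)
  fld <- render_field(states, geometry = field_geometry(160, 160),
                      noise = noise_params("none"), seed = 21)
  dna <- fld$pixels$dna
  seg <- find_nuclei(sliding_parabola(dna))
  expect_length(seg$rois, 1)
  v1 <- extract_features(seg$rois[[1]], sliding_parabola(dna), 0.65)
  expect_length(v1, 240)
  expect_true(all(is.finite(v1)))
  expect_identical(names(v1), feature_catalog()$name)

  # integer translation of the whole field
  shifted <- matrix(0, 160, 160)
  shifted[11:160, 6:160] <- dna[1:150, 1:155]
  seg2 <- find_nuclei(sliding_parabola(shifted))
  v2 <- extract_features(seg2$rois[[1]], sliding_parabola(shifted), 0.65)
  expect_equal(v2, v1, tolerance = 1e-6)
})

test_that("doubling the DNA intensity scales first moments only", {
  states <- data.frame(phase = "G1", dna_content = 2)
  fld <- render_field(states, geometry = field_geometry(128, 128),
                      noise = noise_params("none"), seed = 22)
  dna <- sliding_parabola(fld$pixels$dna)
  seg <- find_nuclei(dna)
  v1 <- extract_features(seg$rois[[1]], dna, 0.65)
  v2 <- extract_features(seg$rois[[1]], dna * 2, 0.65)
  doubled <- paste("Intensity Nucleus",
                   c("Mean", "SD", "Median", "Max", "Min", "Sum",
                     "Quantile50"))
  expect_equal(unname(v2[doubled]), unname(2 * v1[doubled]), tolerance = 1e-9)
  rest <- setdiff(names(v1), doubled)
  expect_equal(v2[rest], v1[rest], tolerance = 1e-6)
})

test_that("a 90-degree rotation leaves the features nearly unchanged", {
  states <- data.frame(phase = "SG2M", dna_content = 3.5)
  fld <- render_field(states, geometry = field_geometry(128, 128),
                      noise = noise_params("none"), seed = 23)
  dna <- sliding_parabola(fld$pixels$dna)
  rot <- t(dna[nrow(dna):1, ])  # 90-degree rotation
  s1 <- find_nuclei(dna); s2 <- find_nuclei(rot)
  v1 <- extract_features(s1$rois[[1]], dna, 0.65)
  v2 <- extract_features(s2$rois[[1]], rot, 0.65)
  scale_ref <- pmax(abs(v1), abs(v2))
  comparable <- scale_ref > 1e-6
  expect_lte(max(abs(v1 - v2)[comparable] / scale_ref[comparable]), 0.02)
})

test_that("the fixture nucleus reproduces its frozen feature vector", {
  golden <- read.csv(test_path("golden_features.csv"), check.names = FALSE)
  states <- data.frame(phase = "earlyS", dna_content = 2.3)
  fld <- render_field(states, geometry = field_geometry(128, 128),
                      noise = noise_params("none"), seed = 7)
  dna <- sliding_parabola(fld$pixels$dna)
  seg <- find_nuclei(dna)
  v <- extract_features(seg$rois[[1]], dna, 0.65)
  expect_equal(length(v), 240)
  expect_identical(names(v), golden$name)
  expect_equal(unname(v), golden$value, tolerance = 1e-6)
})
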