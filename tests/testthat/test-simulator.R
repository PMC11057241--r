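test_that("population sampling honours degenerate and empty inputs", {
  pre <- condition_preset("HeLa", "x", 0, c(1, 0, 0, 0), apoptotic_frac = 0)
  pop <- sample_population(pre, 100, seed = 1)
  expect_equal(nrow(pop), 100)
  expect_true(all(pop$phase == "G1"))
  expect_true(all(pop$dna_content == 2))
  expect_equal(nrow(sample_population(pre, 0, seed = 1)), 0)
  expect_error(condition_preset("HeLa", "x", 0, c(0.5, 0.2, 0.2, 0.2)),
               "summing to 1")
})

test_that("phase fractions follow the preset probabilities", {
  pre <- condition_preset("HeLa", "x", 0, c(0.55, 0.10, 0.30, 0.05))
  pop <- sample_population(pre, 10000, seed = 2)
  # binomial oracle: observed G1 fraction within 3 SDs of 0.55
  sd3 <- 3 * sqrt(0.55 * 0.45 / 10000)
  expect_lt(abs(mean(pop$phase == "G1") - 0.55), sd3)
  # chi-square goodness of fit over 20 seeds; expect <= 1 rejection at 1%
  rejects <- sum(vapply(1:20, function(s) {
    p <- sample_population(pre, 10000, seed = s)
    tab <- table(factor(p$phase, levels = phase_levels()))
    suppressWarnings(
      stats::chisq.test(tab, p = c(0.55, 0.10, 0.30, 0.05))$p.value) < 0.01
  }, logical(1)))
  expect_lte(rejects, 1)
  # fixed seed reproduces draws exactly
  expect_identical(sample_population(pre, 50, seed = 3),
                   sample_population(pre, 50, seed = 3))
})

test_that("phase intervals of DNA content are respected", {
  pre <- condition_preset("HeLa", "x", 0, c(0.25, 0.25, 0.25, 0.25), 0.1)
  pop <- sample_population(pre, 5000, seed = 4)
  rng <- function(ph) range(pop$dna_content[pop$phase == ph])
  expect_true(all(pop$dna_content >= 2 & pop$dna_content <= 4))
  expect_equal(unique(pop$dna_content[pop$phase == "G1"]), 2)
  expect_lte(rng("earlyS")[2], 2.5)
  expect_gte(rng("SG2M")[1], 2.5)
})

test_that("a single noiseless G1 nucleus renders as one gated-G1 object", {
  states <- data.frame(phase = "G1", dna_content = 2)
  fld <- render_field(states, geometry = field_geometry(128, 128),
                      noise = noise_params("none"), seed = 5)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(fld$pixels$dna > 0)))
  expect_equal(max(lab), 1)
  roi <- roi_from_mask(fld$truth_labels == 1)
  mm <- measure_channel_means(roi, fld)
  expect_equal(as.character(gate(mm["red"], mm["green"],
                                 fucci_gating_config("HeLa"))), "G1")
})

test_that("DNA integrated intensity increases with DNA content", {
  pre <- condition_preset("HeLa", "x", 0, c(0.25, 0.25, 0.25, 0.25))
  intens <- c(); contents <- c()
  for (s in 1:6) {
    pop <- sample_population(pre, 170, seed = s)
    fld <- render_field(pop, geometry = field_geometry(768, 768),
                        noise = noise_params("none"), seed = s + 100)
    tot <- vapply(seq_len(nrow(pop)), function(i) {
      sum(fld$pixels$dna[fld$truth_labels == i])
    }, numeric(1))
    intens <- c(intens, tot); contents <- c(contents, pop$dna_content)
  }
  expect_gte(length(intens), 1000)
  expect_gt(cor(contents, intens, method = "spearman"), 0.5)
})

test_that("S/G2/M nuclei are brighter than G1 nuclei (rank-sum)", {
  pre <- condition_preset("HeLa", "x", 0, c(0.5, 0, 0.5, 0))
  pop <- sample_population(pre, 200, seed = 6)
  fld <- render_field(pop, geometry = field_geometry(768, 768), seed = 7)
  tot <- vapply(seq_len(nrow(pop)), function(i) {
    sum(fld$pixels$dna[fld$truth_labels == i])
  }, numeric(1))
  w <- stats::wilcox.test(tot[pop$phase == "SG2M"], tot[pop$phase == "G1"],
                          alternative = "greater")
  expect_lt(w$p.value, 0.001)
})

test_that("apoptotic nuclei have DNA-channel CV above the exclusion threshold", {
  states <- data.frame(phase = rep("apoptotic", 8),
                       dna_content = rep(2.5, 8))
  fld <- render_field(states, geometry = field_geometry(320, 320), seed = 8)
  for (i in seq_len(8)) {
    v <- fld$pixels$dna[fld$truth_labels == i]
    expect_gt(100 * sqrt(mean((v - mean(v))^2)) / mean(v), 70)
  }
})

test_that("noiseless Fucci gating recovers every non-apoptotic truth phase", {
  pre <- condition_preset("HeLa", "x", 0, c(0.4, 0.2, 0.3, 0.1), 0.05)
  pop <- sample_population(pre, 120, seed = 9)
  fld <- render_field(pop, geometry = field_geometry(640, 640),
                      noise = noise_params("none"), seed = 10)
  cfg <- fucci_gating_config("HeLa")
  for (i in which(pop$phase != "apoptotic")) {
    roi <- roi_from_mask(fld$truth_labels == i)
    mm <- measure_channel_means(roi, fld)
    expect_equal(as.character(gate(mm["red"], mm["green"], cfg)),
                 pop$phase[i])
    # margins at least 20% away from both thresholds
    expect_true(abs(fld$truth$red_mean_true[i] - cfg$red_threshold) >=
                  0.2 * cfg$red_threshold)
    expect_true(abs(fld$truth$green_mean_true[i] - cfg$green_threshold) >=
                  0.2 * cfg$green_threshold)
  }
})

test_that("plate simulation writes the expected files, reproducibly", {
  d1 <- file.path(tempdir(), "plate_a"); d2 <- file.path(tempdir(), "plate_b")
  unlink(c(d1, d2), recursive = TRUE)
  pre <- condition_presets("HeLa")["control"]
  simulate_plate(pre, fields_per_condition = 2, out_dir = d1, seed = 11,
                 nuclei_per_field = 12, geometry = field_geometry(160, 160))
  simulate_plate(pre, fields_per_condition = 2, out_dir = d2, seed = 11,
                 nuclei_per_field = 12, geometry = field_geometry(160, 160))
  expect_length(list.files(d1, pattern = "\\.tiff$"), 2)
  meta <- read.csv(file.path(d1, "metadata.csv"))
  expect_equal(nrow(meta), 2)
  truth <- read.csv(file.path(d1, "truth.csv"))
  expect_true(all(c("field_id", "phase", "dna_content") %in% names(truth)))
  # byte-identical across runs with the same seed
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # round trip through the TIFF + sidecar
  fld <- read_field(file.path(d1, paste0(meta$field_id[1], ".tiff")))
  expect_named(fld$pixels, c("dna", "red", "green"))
  expect_equal(dim(fld$pixels$dna), c(160, 160))
})

test_that("drug presets shift the true cycle distribution as expected", {
  frac <- function(cell, name, phase) {
    pre <- condition_presets(cell)[[name]]
    pop <- sample_population(pre, 4000, seed = 12)
    pop <- pop[pop$phase != "apoptotic", ]
    mean(pop$phase == phase)
  }
  # cytotoxic drugs push HeLa toward S/G2/M
  expect_gt(frac("HeLa", "5-FU", "SG2M"), frac("HeLa", "control", "SG2M"))
  expect_gt(frac("HeLa", "SN-38", "SG2M"), frac("HeLa", "control", "SG2M"))
  # the PI3K inhibitor accumulates MCF7 (not HeLa) in G1
  expect_gt(frac("MCF7", "ZSTK474", "G1"), frac("MCF7", "control", "G1"))
})

test_that("a field too small for the population raises a placement error", {
  pre <- condition_preset("HeLa", "x", 0, c(1, 0, 0, 0))
  pop <- sample_population(pre, 60, seed = 13)
  expect_error(render_field(pop, geometry = field_geometry(64, 64), seed = 1),
               "too small")
})
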