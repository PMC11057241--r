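#' Assemble the 240-feature vector of one nucleus
#'
#' Computes, in catalog order: 9 intensity properties, 4 basic morphology
#' properties, 16 SER features (8 filters at scales 1 and 2 px), 4
#' Haralick statistics, and 23 STAR properties on each of 9 image variants
#' (the raw DNA channel and the 8 SER responses at scale 1). All features
#' come from the background-corrected DNA channel only.
#'
#' @param roi A `nucleus_roi`.
#' @param dna_corrected Background-corrected DNA channel matrix.
#' @param pixel_size Pixel size in micrometres (for area/width/length).
#' @param banks Optional precomputed list
#'   `list(s1 = ser_filter_bank(dna, 1), s2 = ser_filter_bank(dna, 2))`;
#'   computed on the fly when `NULL`. Precompute per field when extracting
#'   many nuclei.
#' @param catalog The feature catalog (defaults to [feature_catalog()]).
#' @return Named numeric vector of length 240, all values finite.
#' @examples
#' \donttest{
#' fld <- render_field(sample_population(condition_presets("HeLa")$control,
#'                                       5, 1),
#'                     geometry = field_geometry(192, 192), seed = 1)
#' dna <- sliding_parabola(fld$pixels$dna)
#' seg <- find_nuclei(dna)
#' fv <- extract_features(seg$rois[[1]], dna)
#' length(fv)  # 240
#' }
#' @export
extract_features <- function(roi, dna_corrected, pixel_size = 1,
                             banks = NULL, catalog = feature_catalog()) {
  if (is.null(banks)) {
    banks <- list(s1 = ser_filter_bank(dna_corrected, 1),
                  s2 = ser_filter_bank(dna_corrected, 2))
  }
  bd <- roi_border_distance(roi)
  star_raw <- star_properties(roi, dna_corrected, border_dist = bd)
  names(star_raw) <- paste("Nucleus", names(star_raw))
  star_filt <- unlist(lapply(ser_filter_names(), function(fn) {
    v <- star_properties(roi, banks$s1[[fn]], border_dist = bd)
    names(v) <- paste("Nucleus", names(v), paste0("SER-", fn))
    v
  }))
  out <- c(
    intensity_properties(roi, dna_corrected),
    basic_morphology(roi, pixel_size),
    ser_features(roi, banks$s1, dna_corrected, scale = 1),
    ser_features(roi, banks$s2, dna_corrected, scale = 2),
    haralick_features(roi, dna_corrected),
    star_raw,
    star_filt
  )
  stopifnot(identical(names(out), catalog$name))
  out
}

#' Extract features for every nucleus of a field
#'
#' @param dna_corrected Background-corrected DNA channel.
#' @param nucleus_set A [find_nuclei()] result.
#' @param pixel_size Pixel size in micrometres.
#' @param catalog Feature catalog.
#' @return Numeric matrix, one row per nucleus (rownames = ROI labels),
#'   240 catalog-ordered columns.
#' @export
extract_field_features <- function(dna_corrected, nucleus_set,
                                   pixel_size = 1,
                                   catalog = feature_catalog()) {
  rois <- nucleus_set$rois
  out <- matrix(NA_real_, length(rois), nrow(catalog),
                dimnames = list(vapply(rois, `[[`, 0, "label"), catalog$name))
  if (length(rois) == 0) return(out)
  banks <- list(s1 = ser_filter_bank(dna_corrected, 1),
                s2 = ser_filter_bank(dna_corrected, 2))
  for (i in seq_along(rois)) {
    out[i, ] <- extract_features(rois[[i]], dna_corrected, pixel_size,
                                 banks = banks, catalog = catalog)
  }
  out
}

#' Segment one field and measure every nucleus
#'
#' The per-field workhorse: background-corrects the DNA channel with the
#' sliding-parabola filter, segments nuclei, extracts the 240-feature
#' vector of each, and measures the raw Fucci channel means used for
#' gating.
#'
#' @param field An `image_field`.
#' @param sp_curvature Sliding-parabola curvature.
#' @param catalog Feature catalog.
#' @param ... Passed to [find_nuclei()].
#' @return List with `nuclei` (data.frame: field metadata, label,
#'   centroids, area_px, red_mean, green_mean, dna_cv) and `features`
#'   (matrix from [extract_field_features()]), plus the `nucleus_set`.
#' @export
process_field <- function(field, sp_curvature = 0.003,
                          catalog = feature_catalog(), ...) {
  dna <- sliding_parabola(field$pixels$dna, sp_curvature)
  seg <- find_nuclei(dna, ...)
  feats <- extract_field_features(dna, seg, field$pixel_size_um, catalog)
  n <- length(seg$rois)
  meta <- field$meta %||% data.frame(field_id = field$well_id %||% "field",
                                     well = field$well_id %||% "field")
  nuclei <- cbind(
    meta[rep(1, n), , drop = FALSE],
    data.frame(
      label = if (n) vapply(seg$rois, `[[`, 0, "label") else integer(0),
      centroid_x = if (n) vapply(seg$rois, function(r) r$centroid[2] - 1, 0) else numeric(0),
      centroid_y = if (n) vapply(seg$rois, function(r) r$centroid[1] - 1, 0) else numeric(0),
      area_px = if (n) vapply(seg$rois, `[[`, 0, "area_px") else integer(0)
    )
  )
  if (n > 0) {
    fm <- t(vapply(seg$rois, measure_channel_means, numeric(2), field = field))
    nuclei$red_mean <- fm[, "red"]
    nuclei$green_mean <- fm[, "green"]
    nuclei$dna_cv <- feats[, "Intensity Nucleus CV"]
  } else {
    nuclei$red_mean <- numeric(0)
    nuclei$green_mean <- numeric(0)
    nuclei$dna_cv <- numeric(0)
  }
  rownames(nuclei) <- NULL
  list(nuclei = nuclei, features = feats, nucleus_set = seg)
}

#' Process a list of fields into one nucleus table
#'
#' @param fields List of `image_field` objects (e.g. from
#'   [simulate_fields()]).
#' @param ... Passed to [process_field()].
#' @param progress Print a dot per field to stderr.
#' @return List with `nuclei` (stacked data.frame) and `features`
#'   (stacked matrix, rows aligned with `nuclei`).
#' @export
process_fields <- function(fields, ..., progress = FALSE) {
  res <- lapply(fields, function(f) {
    if (progress) message(".", appendLF = FALSE)
    process_field(f, ...)
  })
  if (progress) message("")
  list(nuclei = do.call(rbind, lapply(res, `[[`, "nuclei")),
       features = do.call(rbind, lapply(res, `[[`, "features")))
}
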