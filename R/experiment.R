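#' Simulate and measure a plate experiment in memory
#'
#' Streaming counterpart of `run_pipeline("all")` up to the feature table:
#' renders one field at a time (identical per-field seeds to
#' [simulate_fields()] with the same arguments), background-corrects,
#' segments, extracts the 240 features, measures Fucci means, and matches
#' segmented nuclei to the ground-truth masks before discarding the pixel
#' data. Suitable for experiments too large to hold as images in memory.
#'
#' @inheritParams simulate_fields
#' @param sp_curvature Sliding-parabola curvature.
#' @param segmentation List of arguments for [find_nuclei()].
#' @param match_iou IoU threshold for truth matching.
#' @return List with:
#' * `nuclei`: data.frame of all segmented nuclei (metadata, centroids,
#'   `red_mean`, `green_mean`, `dna_cv`, and - where a ground-truth match
#'   exists - `truth_phase` and `truth_dna_content`);
#' * `features`: aligned 240-column matrix;
#' * `truth`: stacked per-field ground truth;
#' * `matching`: per-field counts (`n_truth`, `n_pred`, `n_matched`).
#' @export
run_experiment <- function(presets, fields_per_condition = 20, seed = 1,
                           nuclei_per_field = 100,
                           geometry = field_geometry(),
                           render = render_params(),
                           noise = noise_params(), gating = NULL,
                           sp_curvature = 0.003, segmentation = list(),
                           match_iou = 0.5) {
  stopifnot(length(presets) >= 1)
  nuclei <- list(); feats <- list(); truths <- list(); matches <- list()
  fid <- 0L
  for (ci in seq_along(presets)) {
    preset <- presets[[ci]]
    g <- gating %||% fucci_gating_config(preset$cell_line)
    for (fi in seq_len(fields_per_condition)) {
      fid <- fid + 1L
      fseed <- derive_seed(seed, sprintf("field_%d_%d", ci, fi))
      ncell <- with_seed(derive_seed(fseed, "count"),
                         rpois(1, nuclei_per_field))
      states <- sample_population(preset, ncell,
                                  seed = derive_seed(fseed, "pop"))
      well <- sprintf("%s_%02d", names(presets)[ci] %||% preset$drug, fi)
      fld <- render_field(states, geometry = geometry, render = render,
                          noise = noise, gating = g,
                          seed = derive_seed(fseed, "render"),
                          well_id = well)
      fld$meta <- data.frame(field_id = sprintf("f%04d", fid), well = well,
                             cell_line = preset$cell_line, drug = preset$drug,
                             concentration_M = preset$concentration)
      res <- do.call(process_field,
                     c(list(fld, sp_curvature = sp_curvature), segmentation))
      m <- match_truth(res$nucleus_set, fld$truth_labels, match_iou)
      tp <- rep(NA_character_, nrow(res$nuclei))
      td <- rep(NA_real_, nrow(res$nuclei))
      if (nrow(m) > 0) {
        tp[m$pred_label] <- fld$truth$phase[m$truth_id]
        td[m$pred_label] <- fld$truth$dna_content[m$truth_id]
      }
      res$nuclei$truth_phase <- tp
      res$nuclei$truth_dna_content <- td
      nuclei[[fid]] <- res$nuclei
      feats[[fid]] <- res$features
      truths[[fid]] <- cbind(field_id = fld$meta$field_id, fld$truth)
      matches[[fid]] <- data.frame(field_id = fld$meta$field_id,
                                   n_truth = attr(m, "n_truth"),
                                   n_pred = attr(m, "n_pred"),
                                   n_matched = nrow(m))
    }
  }
  list(nuclei = do.call(rbind, nuclei),
       features = do.call(rbind, feats),
       truth = do.call(rbind, truths),
       matching = do.call(rbind, matches))
}
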