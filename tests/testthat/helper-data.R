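# Shared fixtures, built in code and cached for the session.

.cache <- new.env(parent = emptyenv())

# A nucleus_roi from a logical mask (for hand-built feature fixtures).
roi_from_mask <- function(mask, label = 1L) {
  px <- which(mask, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  ccphase:::new_nucleus_roi(label, px,
                            centroid = c(mean(px[, 1]), mean(px[, 2])),
                            area = nrow(px))
}

# A filled digital disc mask.
disc_mask <- function(size, radius, cx = (size + 1) / 2, cy = (size + 1) / 2) {
  outer(seq_len(size), seq_len(size),
        function(r, c) (r - cy)^2 + (c - cx)^2 <= radius^2)
}

# Small mixed-condition HeLa experiment (control + 5-FU), processed through
# segmentation, feature extraction and truth matching; ~700 nuclei.
demo_experiment <- function() {
  if (is.null(.cache$demo)) {
    .cache$demo <- run_experiment(
      condition_presets("HeLa")[c("control", "5-FU")],
      fields_per_condition = 6, seed = 42, nuclei_per_field = 60,
      geometry = field_geometry(384, 384)
    )
  }
  .cache$demo
}

# The demo experiment gated with the HeLa config.
demo_gated <- function() {
  if (is.null(.cache$gated)) {
    demo <- demo_experiment()
    .cache$gated <- gate_dataset(demo$nuclei, demo$features,
                                 fucci_gating_config("HeLa"))
  }
  .cache$gated
}
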