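#' Assign Fucci classes from channel means
#'
#' Hard threshold gates, with the ">=" boundary inclusive exactly as the
#' gate definitions state: G1 when red >= red threshold and
#' green < green threshold; early S when both are at or above their
#' thresholds; S/G2/M when green >= threshold and red below; double
#' negative (DN) otherwise. The four gates partition the (red, green)
#' plane.
#'
#' @param red_mean,green_mean Numeric vectors of mean reporter intensities.
#' @param config A [fucci_gating_config()].
#' @return Factor with levels `G1, earlyS, SG2M, DN`.
#' @examples
#' cfg <- fucci_gating_config("HeLa")
#' gate(1200, 800, cfg)    # G1
#' gate(700, 2500, cfg)    # earlyS (boundaries inclusive)
#' gate(0, 0, cfg)         # DN
#' @export
gate <- function(red_mean, green_mean, config) {
  stopifnot(inherits(config, "fucci_gating_config"))
  red_on <- red_mean >= config$red_threshold
  grn_on <- green_mean >= config$green_threshold
  cls <- ifelse(red_on & !grn_on, "G1",
                ifelse(red_on & grn_on, "earlyS",
                       ifelse(grn_on, "SG2M", "DN")))
  factor(cls, levels = phase_levels())
}

#' Exclude apoptotic nuclei by DNA-channel CV
#'
#' Drops nuclei whose DNA-channel coefficient of variation is strictly
#' greater than the configured percentage (default 70%) when the filter is
#' enabled; fragmented apoptotic nuclei have very heterogeneous intensity
#' and large CVs. Disabled by default for HeLa, enabled for MCF7.
#'
#' @param nuclei data.frame with a `dna_cv` column (percent).
#' @param config A [fucci_gating_config()].
#' @return The retained rows of `nuclei`.
#' @export
apoptotic_filter <- function(nuclei, config) {
  stopifnot(inherits(config, "fucci_gating_config"), "dna_cv" %in% names(nuclei))
  if (!config$cv_exclusion_enabled) return(nuclei)
  nuclei[!(nuclei$dna_cv > config$cv_exclusion_pct), , drop = FALSE]
}

#' One-vs-rest labels for the three prediction tasks
#'
#' Binary indicator columns for "G1 or else", "early S or else" and
#' "S/G2/M or else". DN nuclei are "else" in all three tasks.
#'
#' @param fucci_class Factor or character vector of gated classes.
#' @return Integer matrix with columns `G1`, `earlyS`, `SG2M`.
#' @export
make_binary_labels <- function(fucci_class) {
  cls <- as.character(fucci_class)
  cbind(G1 = as.integer(cls == "G1"),
        earlyS = as.integer(cls == "earlyS"),
        SG2M = as.integer(cls == "SG2M"))
}

#' Gate a processed nucleus table
#'
#' Convenience wrapper: applies the apoptotic CV filter, assigns Fucci
#' classes and attaches the three binary task labels.
#'
#' @param nuclei data.frame from [process_fields()] (needs `red_mean`,
#'   `green_mean`, `dna_cv`).
#' @param features Feature matrix aligned with `nuclei` rows.
#' @param config A [fucci_gating_config()].
#' @return List with filtered, gated `nuclei` (extra columns
#'   `fucci_class`, `label_G1`, `label_earlyS`, `label_SG2M`), the
#'   correspondingly filtered `features` matrix, and a `report` list of
#'   class and exclusion counts.
#' @export
gate_dataset <- function(nuclei, features, config) {
  n0 <- nrow(nuclei)
  keep <- if (config$cv_exclusion_enabled) {
    !(nuclei$dna_cv > config$cv_exclusion_pct)
  } else {
    rep(TRUE, n0)
  }
  nuclei <- nuclei[keep, , drop = FALSE]
  features <- features[keep, , drop = FALSE]
  nuclei$fucci_class <- gate(nuclei$red_mean, nuclei$green_mean, config)
  lab <- make_binary_labels(nuclei$fucci_class)
  nuclei$label_G1 <- lab[, "G1"]
  nuclei$label_earlyS <- lab[, "earlyS"]
  nuclei$label_SG2M <- lab[, "SG2M"]
  list(nuclei = nuclei, features = features,
       report = list(n_measured = n0, n_excluded = n0 - nrow(nuclei),
                     class_counts = as.list(table(nuclei$fucci_class))))
}

#' Sample disjoint train/validation sets and min-max normalize
#'
#' Draws a uniform random sample without replacement of
#' `n_train + n_val` rows, splits it into disjoint training and validation
#' partitions, and rescales every feature to \[0, 1\] using the minimum
#' and maximum of the *training* rows only (constant features map to 0);
#' validation values falling outside the training range are clipped to
#' \[0, 1\]. Set `bounds = "all"` to fit the bounds on both partitions
#' instead.
#'
#' @param features Numeric feature matrix.
#' @param nuclei data.frame aligned with `features` (carried through).
#' @param n_train,n_val Partition sizes (defaults 7500 / 2500).
#' @param seed Integer seed; sampling is reproducible.
#' @param bounds `"train"` (default) or `"all"`.
#' @return An object of class `dataset_split`: list with `train_x`,
#'   `val_x` (normalized matrices), `train_info`, `val_info` (nucleus
#'   rows), and `bounds` (per-feature min/max used).
#' @export
sample_and_normalize <- function(features, nuclei, n_train = 7500,
                                 n_val = 2500, seed = 1,
                                 bounds = c("train", "all")) {
  bounds <- match.arg(bounds)
  n <- nrow(features)
  if (n < n_train + n_val) {
    stop(sprintf("need at least %d rows, have %d", n_train + n_val, n),
         call. = FALSE)
  }
  if (anyNA(features)) stop("feature matrix contains missing values",
                            call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_train + n_val))
  tr <- idx[seq_len(n_train)]
  va <- idx[n_train + seq_len(n_val)]
  fit_rows <- if (bounds == "train") tr else c(tr, va)
  mins <- apply(features[fit_rows, , drop = FALSE], 2, min)
  maxs <- apply(features[fit_rows, , drop = FALSE], 2, max)
  rng <- maxs - mins
  norm <- function(x) {
    out <- sweep(sweep(x, 2, mins, `-`), 2, ifelse(rng == 0, 1, rng), `/`)
    out[, rng == 0] <- 0
    clamp(out, 0, 1)
  }
  structure(list(
    train_x = norm(features[tr, , drop = FALSE]),
    val_x = norm(features[va, , drop = FALSE]),
    train_info = nuclei[tr, , drop = FALSE],
    val_info = nuclei[va, , drop = FALSE],
    bounds = data.frame(feature = colnames(features), min = mins, max = maxs,
                        row.names = NULL)
  ), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d x %d, validation %d x %d\n",
              nrow(x$train_x), ncol(x$train_x),
              nrow(x$val_x), ncol(x$val_x)))
  invisible(x)
}
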