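#' Default pipeline configuration
#'
#' The configuration that reproduces the package's default experiment: a
#' HeLa-like plate with the built-in control and five high-dose drug
#' presets, 20 fields per condition of ~100 nuclei each (~12 000 nuclei),
#' the default noise model, a 7500/2500 train/validation split, and
#' 10-fold cross-validation. The default cross-validated families are
#' logistic regression (all variables) and random forest; the slower
#' families (SVM, backward-stepwise regression, neural network) are
#' enabled by adding them to `cv_families`.
#'
#' @param ... Overrides merged into the defaults (nested lists are merged
#'   recursively).
#' @return Named list, the pipeline configuration.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    cell_line = "HeLa",
    fields_per_condition = 20,
    nuclei_per_field = 100,
    geometry = list(width = 512, height = 512, pixel_size_um = 0.65),
    noise = list(profile = "default"),
    sp_curvature = 0.003,
    segmentation = list(smooth_sigma = 2, min_area = 50,
                        watershed_tolerance = 1),
    n_train = 7500,
    n_val = 2500,
    cv_families = c("logreg_all", "random_forest"),
    cv_folds = 10,
    tasks = c("G1", "earlyS", "SG2M"),
    model_params = list(random_forest = list(num_trees = 500))
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override [default_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  over <- yaml::read_yaml(path)
  cfg <- default_config()
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  cfg
}

cfg_presets <- function(config) {
  if (!is.null(config$presets)) {
    lapply(config$presets, function(p) {
      condition_preset(p$cell_line %||% config$cell_line, p$drug,
                       p$concentration, unlist(p$phase_probs),
                       p$apoptotic_frac %||% 0)
    })
  } else {
    condition_presets(config$cell_line)
  }
}

cfg_geometry <- function(config) {
  do.call(field_geometry, config$geometry)
}

cfg_noise <- function(config) {
  do.call(noise_params, config$noise)
}

cfg_gating <- function(config) {
  do.call(fucci_gating_config,
          c(list(cell_line = config$cell_line), config$gating))
}

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' needs missing artifact: %s", stage, path),
         call. = FALSE)
  }
  path
}

log_line <- function(out_dir, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message("[ccphase] ", msg)
  cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "",
      file = file.path(out_dir, "run.log"), append = TRUE)
}

read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, feature_catalog()$name, drop = FALSE])
  rownames(m) <- df$nucleus_uid
  m
}

stage_simulate <- function(config, out_dir) {
  presets <- cfg_presets(config)
  simulate_plate(presets, config$fields_per_condition,
                 out_dir = file.path(out_dir, "images"),
                 seed = derive_seed(config$seed, "simulate"),
                 nuclei_per_field = config$nuclei_per_field,
                 geometry = cfg_geometry(config), noise = cfg_noise(config))
  invisible(NULL)
}

stage_segment <- function(config, out_dir) {
  img_dir <- need_artifact(file.path(out_dir, "images", "metadata.csv"),
                           "segment")
  meta <- read.csv(dirname(img_dir) |> file.path("metadata.csv"))
  lab_dir <- file.path(out_dir, "labels")
  dir.create(lab_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    f <- read_field(file.path(out_dir, "images",
                              paste0(meta$field_id[i], ".tiff")))
    dna <- sliding_parabola(f$pixels$dna, config$sp_curvature)
    seg <- do.call(find_nuclei, c(list(dna), config$segmentation))
    tiff::writeTIFF(seg$labels / 65535,
                    file.path(lab_dir, paste0(meta$field_id[i], "_labels.tiff")),
                    bits.per.sample = 16, compression = "none")
    n <- length(seg$rois)
    if (n == 0) next
    fm <- t(vapply(seg$rois, measure_channel_means, numeric(2), field = f))
    rows[[i]] <- data.frame(
      field_id = meta$field_id[i],
      label = vapply(seg$rois, `[[`, 0, "label"),
      centroid_x = vapply(seg$rois, function(r) r$centroid[2] - 1, 0),
      centroid_y = vapply(seg$rois, function(r) r$centroid[1] - 1, 0),
      area_px = vapply(seg$rois, `[[`, 0, "area_px"),
      red_mean = fm[, "red"], green_mean = fm[, "green"]
    )
  }
  nuclei <- do.call(rbind, rows)
  write.csv(nuclei, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
  invisible(NULL)
}

stage_extract <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "nuclei.csv"), "extract")
  meta <- read.csv(file.path(out_dir, "images", "metadata.csv"))
  nuclei <- read.csv(file.path(out_dir, "nuclei.csv"))
  catalog <- feature_catalog()
  feats <- list(); cvs <- list()
  for (i in seq_len(nrow(meta))) {
    fid <- meta$field_id[i]
    f <- read_field(file.path(out_dir, "images", paste0(fid, ".tiff")))
    labs <- round(tiff::readTIFF(
      need_artifact(file.path(out_dir, "labels", paste0(fid, "_labels.tiff")),
                    "extract")) * 65535)
    seg <- nucleus_set_from_labels(labs)
    dna <- sliding_parabola(f$pixels$dna, config$sp_curvature)
    fm <- extract_field_features(dna, seg, f$pixel_size_um, catalog)
    if (nrow(fm) > 0) {
      rownames(fm) <- paste0(fid, ":", vapply(seg$rois, `[[`, 0, "label"))
      feats[[i]] <- fm
    }
  }
  fmat <- do.call(rbind, feats)
  df <- data.frame(nucleus_uid = rownames(fmat), check.names = FALSE)
  df[, colnames(fmat)] <- fmat
  write.csv(df, file.path(out_dir, "features.csv"), row.names = FALSE)
  write_catalog_json(file.path(out_dir, "catalog.json"), catalog)
  invisible(NULL)
}

stage_gate <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "nuclei.csv"), "gate")
  need_artifact(file.path(out_dir, "features.csv"), "gate")
  nuclei <- read.csv(file.path(out_dir, "nuclei.csv"))
  meta <- read.csv(file.path(out_dir, "images", "metadata.csv"))
  nuclei <- merge(nuclei, meta, by = "field_id", sort = FALSE)
  fmat <- read_features_csv(file.path(out_dir, "features.csv"))
  nuclei$nucleus_uid <- paste0(nuclei$field_id, ":", nuclei$label)
  fmat <- fmat[nuclei$nucleus_uid, , drop = FALSE]
  nuclei$dna_cv <- fmat[, "Intensity Nucleus CV"]
  gating <- cfg_gating(config)
  gated <- gate_dataset(nuclei, fmat, gating)
  write.csv(gated$nuclei, file.path(out_dir, "gated.csv"), row.names = FALSE)
  jsonlite::write_json(gated$report, file.path(out_dir, "gating_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_split <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "gated.csv"), "split")
  gated <- read.csv(file.path(out_dir, "gated.csv"))
  fmat <- read_features_csv(file.path(out_dir, "features.csv"))
  fmat <- fmat[gated$nucleus_uid, , drop = FALSE]
  split <- sample_and_normalize(fmat, gated, n_train = config$n_train,
                                n_val = config$n_val,
                                seed = derive_seed(config$seed, "split"))
  write_split_csv <- function(x, info, path) {
    df <- info
    df[, colnames(x)] <- x
    write.csv(df, path, row.names = FALSE)
  }
  write_split_csv(split$train_x, split$train_info,
                  file.path(out_dir, "train.csv"))
  write_split_csv(split$val_x, split$val_info,
                  file.path(out_dir, "validation.csv"))
  jsonlite::write_json(split$bounds, file.path(out_dir, "norm_bounds.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

read_split_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, feature_catalog()$name, drop = FALSE])
  info <- df[, setdiff(names(df), feature_catalog()$name), drop = FALSE]
  list(x = x, info = info)
}

stage_train <- function(config, out_dir) {
  tr <- read_split_csv(need_artifact(file.path(out_dir, "train.csv"), "train"))
  seed <- derive_seed(config$seed, "train")
  cv_rows <- list()
  models <- list()
  selection <- list()
  for (task in config$tasks) {
    y <- tr$info[[paste0("label_", task)]]
    results <- lapply(config$cv_families, function(fam) {
      params <- do.call(model_params,
                        c(list(fam), config$model_params[[fam]] %||% list()))
      cross_validate(fam, tr$x, y, k = config$cv_folds,
                     seed = derive_seed(seed, paste0(task, "_cv")),
                     params = params, task = task)
    })
    for (r in results) {
      cv_rows[[length(cv_rows) + 1]] <- data.frame(
        task = task, family = r$family,
        fold = seq_along(r$fold_accuracies), accuracy = r$fold_accuracies)
    }
    best <- select_best(results)
    selection[[task]] <- list(
      selected = best,
      cv_mean_accuracy = stats::setNames(
        lapply(results, `[[`, "mean_accuracy"),
        vapply(results, `[[`, "", "family"))
    )
    params <- do.call(model_params,
                      c(list(best), config$model_params[[best]] %||% list()))
    models[[task]] <- train_classifier(best, tr$x, y, params = params,
                                       seed = derive_seed(seed, task))
  }
  write.csv(do.call(rbind, cv_rows), file.path(out_dir, "cv_results.csv"),
            row.names = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  for (task in names(models)) {
    saveRDS(models[[task]],
            file.path(out_dir, "models", paste0(task, ".rds")))
  }
  jsonlite::write_json(selection, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_evaluate <- function(config, out_dir) {
  va <- read_split_csv(need_artifact(file.path(out_dir, "validation.csv"),
                                     "evaluate"))
  selection <- jsonlite::read_json(
    need_artifact(file.path(out_dir, "selection.json"), "evaluate"),
    simplifyVector = TRUE)
  report <- list()
  imp_rows <- list()
  for (task in config$tasks) {
    model <- readRDS(need_artifact(
      file.path(out_dir, "models", paste0(task, ".rds")), "evaluate"))
    ev <- evaluate_model(model, va$x, va$info[[paste0("label_", task)]])
    report[[task]] <- list(selected = selection[[task]]$selected,
                           cv_mean_accuracy = selection[[task]]$cv_mean_accuracy,
                           validation = unclass(ev))
    if (model$family == "random_forest") {
      imp <- feature_importance(model)
      imp_rows[[task]] <- cbind(task = task, rank = seq_len(nrow(imp$ranking)),
                                imp$ranking)
    }
  }
  imp <- do.call(rbind, imp_rows) %||%
    data.frame(task = character(0), rank = integer(0),
               feature = character(0), importance = numeric(0))
  write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_report <- function(config, out_dir) {
  va <- read_split_csv(need_artifact(file.path(out_dir, "validation.csv"),
                                     "report"))
  need_artifact(file.path(out_dir, "model_report.json"), "report")
  fmat <- read_features_csv(file.path(out_dir, "features.csv"))
  raw_val <- fmat[va$info$nucleus_uid, , drop = FALSE]
  pred <- lapply(c("G1", "SG2M"), function(task) {
    model <- readRDS(need_artifact(
      file.path(out_dir, "models", paste0(task, ".rds")), "report"))
    predict_prob(model, va$x)
  })
  summary <- summarize_conditions(va$info, pred[[1]], pred[[2]])
  write.csv(summary, file.path(out_dir, "condition_summary.csv"),
            row.names = FALSE)
  comparisons <- top_feature_comparisons(raw_val, va$info$fucci_class)
  write.csv(comparisons, file.path(out_dir, "group_comparisons.csv"),
            row.names = FALSE)
  p1 <- plot_condition_summary(summary,
                               file.path(out_dir, "condition_summary.png"))
  p2 <- plot_feature_boxplots(raw_val, va$info$fucci_class,
                              path = file.path(out_dir, "feature_boxplots.png"))
  model_report <- jsonlite::read_json(file.path(out_dir, "model_report.json"),
                                      simplifyVector = TRUE)
  write_html_report(file.path(out_dir, "report.html"),
                    condition_summary = summary,
                    model_report = model_report,
                    comparisons = comparisons, images = c(p1, p2))
  invisible(NULL)
}

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`) of the analysis pipeline against an
#' output directory that accumulates the artifacts: simulated TIFFs and
#' ground truth, segmentation masks and `nuclei.csv`, `features.csv`
#' (240 catalog-ordered columns), gated tables, normalized
#' `train.csv`/`validation.csv`, `cv_results.csv`, fitted models,
#' `model_report.json`, `importance.csv`, condition summaries and an HTML
#' report. A `run_manifest.json` with the configuration, stage wall-clock
#' times and artifact checksums is updated after every invocation.
#' Stages fail with a dependency error naming the missing artifact when
#' run out of order.
#'
#' @param stage One of `simulate`, `segment`, `extract`, `gate`, `split`,
#'   `train`, `evaluate`, `report`, `all`.
#' @param config Configuration from [default_config()] or [load_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = "all", config = default_config(),
                         out_dir = "ccphase_run") {
  stages <- c("simulate", "segment", "extract", "gate", "split", "train",
              "evaluate", "report")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  for (s in todo) {
    log_line(out_dir, "stage %s ...", s)
    t0 <- proc.time()[["elapsed"]]
    switch(s,
      simulate = stage_simulate(config, out_dir),
      segment = stage_segment(config, out_dir),
      extract = stage_extract(config, out_dir),
      gate = stage_gate(config, out_dir),
      split = stage_split(config, out_dir),
      train = stage_train(config, out_dir),
      evaluate = stage_evaluate(config, out_dir),
      report = stage_report(config, out_dir)
    )
    timings[[s]] <- round(proc.time()[["elapsed"]] - t0, 2)
    log_line(out_dir, "stage %s done in %.1fs", s, timings[[s]])
  }
  arts <- list.files(out_dir, pattern = "\\.(csv|json|html)$",
                     full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ccphase")),
    seed = config$seed,
    config = config,
    stages_run = todo,
    wall_clock_s = timings,
    artifact_md5 = as.list(tools::md5sum(arts))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
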