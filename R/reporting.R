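#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of a location shift between two samples.
#' Reports the rank-sum statistic of `x` (midranks for ties). The p-value
#' is exact (by enumeration of rank assignments) when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `statistic` (rank sum of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 exactly
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(x); n <- length(y)
  ranks <- rank(c(x, y))
  statistic <- sum(ranks[seq_len(m)])
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (m + n) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = statistic, p_value = min(wt$p.value, 1),
       method = if (exact) "exact" else "normal")
}

#' Per-condition phase distributions, gated and predicted
#'
#' For each (cell line, drug, concentration) condition: the number of
#' nuclei, the fraction of each Fucci-gated class, and the fraction of
#' nuclei called positive by the G1 and S/G2/M prediction models.
#'
#' @param nuclei Gated nucleus data.frame with metadata columns
#'   `cell_line`, `drug`, `concentration_M` and a `fucci_class` column.
#' @param pred_g1,pred_sg2m Optional numeric vectors of model scores
#'   (class-1 probability) aligned with `nuclei`; fractions are computed
#'   at cutoff 0.5. Omit to report gated fractions only.
#' @return data.frame with one row per condition: `cell_line`, `drug`,
#'   `concentration_M`, `n_nuclei`, `frac_G1`, `frac_earlyS`, `frac_SG2M`,
#'   `frac_DN`, and (when scores are given) `pred_G1_fraction`,
#'   `pred_SG2M_fraction`. Fractions are `NA` for empty conditions.
#' @export
summarize_conditions <- function(nuclei, pred_g1 = NULL, pred_sg2m = NULL) {
  need <- c("cell_line", "drug", "concentration_M", "fucci_class")
  if (!all(need %in% names(nuclei))) {
    stop("nuclei table lacks metadata columns: ",
         paste(setdiff(need, names(nuclei)), collapse = ", "), call. = FALSE)
  }
  key <- interaction(nuclei$cell_line, nuclei$drug, nuclei$concentration_M,
                     drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(nuclei)), key)
  rows <- lapply(groups, function(idx) {
    g <- nuclei[idx, , drop = FALSE]
    n <- nrow(g)
    fr <- as.numeric(table(factor(g$fucci_class, levels = phase_levels()))) / n
    out <- data.frame(
      cell_line = g$cell_line[1], drug = g$drug[1],
      concentration_M = g$concentration_M[1], n_nuclei = n,
      frac_G1 = fr[1], frac_earlyS = fr[2], frac_SG2M = fr[3], frac_DN = fr[4]
    )
    if (!is.null(pred_g1)) {
      out$pred_G1_fraction <- mean(pred_g1[idx] >= 0.5)
    }
    if (!is.null(pred_sg2m)) {
      out$pred_SG2M_fraction <- mean(pred_sg2m[idx] >= 0.5)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_line, out$drug, out$concentration_M), , drop = FALSE]
}

#' Compare top-ranked features between G1 and S/G2/M nuclei
#'
#' For each requested feature: group medians and means for the Fucci-gated
#' G1 and S/G2/M validation nuclei and the two-sided Wilcoxon rank-sum
#' p-value. These are the box-plot comparisons for the features at the top
#' of the random-forest importance ranking (total intensity and nuclear
#' area).
#'
#' @param features Feature matrix of the validation set.
#' @param fucci_class Gated classes aligned with `features` rows.
#' @param feature_names Features to compare.
#' @return data.frame with one row per feature: group sizes,
#'   medians, means, rank-sum statistic and p-value. Comparisons with an
#'   empty group are reported with `NA` statistics.
#' @export
top_feature_comparisons <- function(features, fucci_class,
                                    feature_names = c("Intensity Nucleus Sum",
                                                      "Nucleus Area")) {
  cls <- as.character(fucci_class)
  rows <- lapply(feature_names, function(fn) {
    x <- features[cls == "G1", fn]
    y <- features[cls == "SG2M", fn]
    base <- data.frame(feature = fn, n_G1 = length(x), n_SG2M = length(y),
                       median_G1 = stats::median(x), median_SG2M = stats::median(y),
                       mean_G1 = mean(x), mean_SG2M = mean(y))
    if (length(x) == 0 || length(y) == 0) {
      base$rank_sum <- NA_real_; base$p_value <- NA_real_
    } else {
      wt <- wilcoxon_rank_sum(x, y)
      base$rank_sum <- wt$statistic
      base$p_value <- wt$p_value
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Box plots of top features by gated class
#'
#' @param features,fucci_class As in [top_feature_comparisons()].
#' @param feature_names Features to plot.
#' @param path Output image path (PNG).
#' @return `path`, invisibly.
#' @export
plot_feature_boxplots <- function(features, fucci_class,
                                  feature_names = c("Intensity Nucleus Sum",
                                                    "Nucleus Area"),
                                  path = "feature_boxplots.png") {
  cls <- as.character(fucci_class)
  keep <- cls %in% c("G1", "SG2M")
  df <- do.call(rbind, lapply(feature_names, function(fn) {
    data.frame(feature = fn, class = cls[keep], value = features[keep, fn])
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "Fucci-gated class", y = "feature value") +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = 6, height = 3.2, dpi = 120)
  invisible(path)
}

#' Stacked-bar chart of per-condition phase distributions
#'
#' @param summary Output of [summarize_conditions()].
#' @param path Output image path (PNG).
#' @return `path`, invisibly.
#' @export
plot_condition_summary <- function(summary, path = "condition_summary.png") {
  long <- do.call(rbind, lapply(phase_levels(), function(ph) {
    data.frame(condition = paste(summary$drug, signif(summary$concentration_M, 2)),
               phase = ph, fraction = summary[[paste0("frac_", ph)]])
  }))
  long$phase <- factor(long$phase, levels = rev(phase_levels()))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$condition,
                                          y = .data$fraction,
                                          fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of nuclei") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 120)
  invisible(path)
}

#' Write a self-contained HTML report
#'
#' A single HTML file with the per-condition phase distributions, the
#' model selection and validation metrics, the top-importance features,
#' and the group comparisons.
#'
#' @param path Output HTML path.
#' @param condition_summary Output of [summarize_conditions()].
#' @param model_report List as produced by the pipeline's train stage.
#' @param comparisons Output of [top_feature_comparisons()].
#' @param images Character vector of image paths to embed by reference.
#' @return `path`, invisibly.
#' @export
write_html_report <- function(path, condition_summary = NULL,
                              model_report = NULL, comparisons = NULL,
                              images = character(0)) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", as.character(x)))
  tab <- function(df) {
    if (is.null(df)) return("")
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 4))
    paste0("<table border='1' cellpadding='4' cellspacing='0'><tr>",
           paste0("<th>", esc(names(df)), "</th>", collapse = ""), "</tr>",
           paste(apply(df, 1, function(r) {
             paste0("<tr>", paste0("<td>", esc(r), "</td>", collapse = ""),
                    "</tr>")
           }), collapse = "\n"),
           "</table>")
  }
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Cell-cycle phase prediction report</title></head><body>",
    "<h1>Cell-cycle phase prediction report</h1>",
    if (!is.null(condition_summary)) c(
      "<h2>Phase distribution per condition</h2>", tab(condition_summary)),
    if (!is.null(model_report)) c(
      "<h2>Model selection and validation</h2>",
      paste0("<pre>", esc(jsonlite::toJSON(model_report, auto_unbox = TRUE,
                                           pretty = TRUE, digits = 6)),
             "</pre>")),
    if (!is.null(comparisons)) c(
      "<h2>Top-feature group comparisons (G1 vs S/G2/M)</h2>",
      tab(comparisons)),
    vapply(images, function(img) {
      sprintf("<p><img src='%s' style='max-width:100%%'></p>", basename(img))
    }, ""),
    "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}
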