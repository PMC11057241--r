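#' Sliding-parabola background correction
#'
#' Estimates the image background as the grey-scale opening with a
#' paraboloid structuring element `b(u, v) = -curvature * (u^2 + v^2)`
#' (the classic "rolling paraboloid") and subtracts it, clipping at zero.
#' Because the paraboloid is additively separable, the opening is computed
#' exactly in O(n) per pixel row/column with a lower-envelope min-plus
#' convolution. Smaller curvatures correspond to flatter (wider) parabolas
#' and remove broader background structure; the curvature must exceed the
#' background's own curvature for the background to be tracked, and stay
#' well below `peak / radius^2` of a nucleus for nuclei to be preserved.
#'
#' @param image Numeric matrix (one channel).
#' @param curvature Parabola steepness in intensity counts per px^2
#'   (> 0). Default 0.003 suits 16-bit fields with ~60-count background
#'   domes and nuclei brighter than ~1000 counts.
#' @return Matrix of the same shape: `pmax(image - opening, 0)`. The
#'   result is never negative and never exceeds the input.
#' @examples
#' img <- matrix(100, 32, 32); img[10:14, 10:14] <- 500
#' out <- sliding_parabola(img, curvature = 0.1)
#' @export
sliding_parabola <- function(image, curvature = 0.003) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(curvature) || length(curvature) != 1 || curvature <= 0) {
    stop("`curvature` must be a single positive number", call. = FALSE)
  }
  bg <- cpp_parabola_opening(image, curvature)
  pmax(image - bg, 0)
}

new_nucleus_roi <- function(label, pixels, centroid, area) {
  structure(list(
    label = label,
    pixels = pixels,  # 2-column matrix (row, col), 1-based
    bbox = c(min(pixels[, 1]), min(pixels[, 2]),
             max(pixels[, 1]), max(pixels[, 2])),
    centroid = centroid, area_px = area
  ), class = "nucleus_roi")
}

#' Segment nuclei in a background-corrected DNA channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, then (when
#' `split_touching`) a distance-transform watershed to separate touching
#' nuclei. Objects smaller than `min_area` px and (by default) objects
#' touching the field border are discarded, since partial nuclei would
#' distort area and intensity features.
#'
#' @param dna_corrected Non-negative numeric matrix (output of
#'   [sliding_parabola()]).
#' @param smooth_sigma Gaussian sigma (px) before thresholding.
#' @param min_area Minimum object area in px.
#' @param split_touching Split touching objects by watershed.
#' @param exclude_border Discard objects touching the field border.
#' @param watershed_tolerance Minimum distance-map depth (px) between two
#'   objects for them to be split.
#' @return An object of class `nucleus_set`: list with `labels` (integer
#'   matrix, 0 = background, labels 1..n in scan order) and `rois` (list of
#'   `nucleus_roi`: label, pixel coordinates, bbox, centroid, area). A
#'   blank field yields zero ROIs.
#' @export
find_nuclei <- function(dna_corrected, smooth_sigma = 2, min_area = 50,
                        split_touching = TRUE, exclude_border = TRUE,
                        watershed_tolerance = 1) {
  if (!is.matrix(dna_corrected)) {
    stop("`dna_corrected` must be a matrix", call. = FALSE)
  }
  if (any(dna_corrected < 0)) {
    stop("`dna_corrected` must be non-negative", call. = FALSE)
  }
  h <- nrow(dna_corrected); w <- ncol(dna_corrected)
  empty <- function() {
    structure(list(labels = matrix(0L, h, w), rois = list()),
              class = "nucleus_set")
  }
  mx <- max(dna_corrected)
  if (mx == 0) return(empty())
  sm <- as.matrix(EBImage::gblur(dna_corrected / mx, sigma = smooth_sigma))
  thr <- EBImage::otsu(EBImage::Image(clamp(sm, 0, 1)), range = c(0, 1))
  bin <- sm > thr
  if (!any(bin)) return(empty())
  bin <- as.matrix(EBImage::fillHull(EBImage::Image(bin * 1)))
  labels <- if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(bin))
    as.matrix(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))
  } else {
    as.matrix(EBImage::bwlabel(EBImage::Image(bin)))
  }
  storage.mode(labels) <- "integer"
  if (max(labels) == 0) return(empty())
  # drop small and border-touching objects, relabel sequentially
  keep <- tabulate(labels[labels > 0], nbins = max(labels)) >= min_area
  if (exclude_border) {
    border <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
    keep[border[border > 0]] <- FALSE
  }
  old <- which(keep)
  if (length(old) == 0) return(empty())
  remap <- integer(max(labels))
  remap[old] <- seq_along(old)
  labels[labels > 0] <- remap[labels[labels > 0]]
  nucleus_set_from_labels(labels)
}

#' Rebuild a nucleus set from a label image
#'
#' Inverse of the `labels` component of a [find_nuclei()] result; used
#' when segmentation masks are reloaded from disk. Labels are renumbered
#' 1..n in ascending order of the original labels.
#'
#' @param labels Integer matrix, 0 = background.
#' @return A `nucleus_set`.
#' @export
nucleus_set_from_labels <- function(labels) {
  h <- nrow(labels)
  storage.mode(labels) <- "integer"
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(structure(list(labels = labels, rois = list()),
                     class = "nucleus_set"))
  }
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  lab <- labels[idx]
  ord <- order(lab, idx)
  rr <- rr[ord]; cc <- cc[ord]; lab <- lab[ord]
  splits <- split(seq_along(lab), lab)
  rois <- vector("list", length(splits))
  relab <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(splits)) {
    s <- splits[[k]]
    px <- cbind(row = rr[s], col = cc[s])
    relab[px] <- k
    rois[[k]] <- new_nucleus_roi(k, px,
                                 centroid = c(mean(px[, 1]), mean(px[, 2])),
                                 area = nrow(px))
  }
  structure(list(labels = relab, rois = rois), class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei in a %d x %d field\n",
              length(x$rois), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Mean raw channel intensities within one nucleus
#'
#' Arithmetic mean of the raw (uncorrected) pixel values of each channel
#' over the ROI mask; Fucci gating operates on these means.
#'
#' @param roi A `nucleus_roi`.
#' @param field An `image_field` (or any list with a `pixels` list of
#'   matrices).
#' @param channels Which channels to measure.
#' @return Named numeric vector of per-channel means.
#' @export
measure_channel_means <- function(roi, field, channels = c("red", "green")) {
  px <- roi$pixels
  m <- field$pixels[[1]]
  if (any(px[, 1] < 1 | px[, 1] > nrow(m) | px[, 2] < 1 | px[, 2] > ncol(m))) {
    stop("ROI mask outside field bounds", call. = FALSE)
  }
  vapply(channels, function(ch) {
    mean(field$pixels[[ch]][px])
  }, numeric(1))
}

#' Match segmented nuclei to ground-truth masks
#'
#' Greedy one-to-one matching by intersection-over-union between the truth
#' label image of a simulated field and a segmentation result.
#'
#' @param nucleus_set A [find_nuclei()] result.
#' @param truth_labels Integer matrix of ground-truth masks.
#' @param min_iou Minimum IoU for a match.
#' @return data.frame with one row per matched pair: `truth_id`,
#'   `pred_label`, `iou`; plus attributes `n_truth` and `n_pred` for
#'   precision/recall computation.
#' @export
match_truth <- function(nucleus_set, truth_labels, min_iou = 0.5) {
  pred <- nucleus_set$labels
  both <- truth_labels > 0 | pred > 0
  tl <- truth_labels[both]; pl <- pred[both]
  n_t <- max(truth_labels); n_p <- max(pred)
  out <- data.frame(truth_id = integer(0), pred_label = integer(0),
                    iou = numeric(0))
  if (n_t > 0 && n_p > 0) {
    inter <- table(factor(tl, levels = seq_len(n_t)),
                   factor(pl, levels = seq_len(n_p)))
    inter <- unclass(inter)[, , drop = FALSE]
    area_t <- tabulate(truth_labels[truth_labels > 0], nbins = n_t)
    area_p <- tabulate(pred[pred > 0], nbins = n_p)
    iou <- inter / (outer(area_t, area_p, `+`) - inter)
    # greedy: best IoU first, each truth/pred used once
    repeat {
      best <- which.max(iou)
      if (length(best) == 0 || iou[best] < min_iou) break
      ti <- ((best - 1) %% n_t) + 1
      pj <- ((best - 1) %/% n_t) + 1
      out <- rbind(out, data.frame(truth_id = ti, pred_label = pj,
                                   iou = iou[best]))
      iou[ti, ] <- -1
      iou[, pj] <- -1
    }
  }
  attr(out, "n_truth") <- n_t
  attr(out, "n_pred") <- n_p
  out
}
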