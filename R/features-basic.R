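#' Intensity properties of one nucleus
#'
#' The nine standard intensity descriptors of the DNA channel within the
#' ROI: mean, population standard deviation, median, max, min, sum,
#' coefficient of variation (percent; 0 when the mean is 0), quantile-50%
#' (equal to the median by definition but kept as a separate catalog
#' slot), and Michelson contrast `(max - min) / (max + min)` (0 when
#' `max + min` is 0).
#'
#' @param roi A `nucleus_roi`.
#' @param dna Numeric matrix (DNA channel).
#' @return Named numeric vector of length 9 in catalog order.
#' @export
intensity_properties <- function(roi, dna) {
  v <- dna[roi$pixels]
  if (length(v) == 0) stop("empty ROI mask", call. = FALSE)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))  # population SD, consistent with CV
  mx <- max(v); mn <- min(v)
  med <- stats::median(v)
  c("Intensity Nucleus Mean" = m,
    "Intensity Nucleus SD" = s,
    "Intensity Nucleus Median" = med,
    "Intensity Nucleus Max" = mx,
    "Intensity Nucleus Min" = mn,
    "Intensity Nucleus Sum" = sum(v),
    "Intensity Nucleus CV" = if (m == 0) 0 else 100 * s / m,
    "Intensity Nucleus Quantile50" = med,
    "Intensity Nucleus Contrast" = if (mx + mn == 0) 0 else (mx - mn) / (mx + mn))
}

# Crofton-corrected perimeter: pi/4 times the count of exposed 4-neighbour
# edges, which is asymptotically exact for smooth convex outlines.
mask_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  exposed <- (core & !pad[1:h, 2:(w + 1)]) + (core & !pad[3:(h + 2), 2:(w + 1)]) +
    (core & !pad[2:(h + 1), 1:w]) + (core & !pad[2:(h + 1), 3:(w + 2)])
  (pi / 4) * sum(exposed)
}

#' Basic morphology of one nucleus
#'
#' Area (um^2), roundness, width and length. Length and width are the full
#' major/minor axis lengths of the mask's second-moment ellipse
#' (`4 * sqrt(eigenvalue)`, the convention that makes a solid disc of
#' radius r have length 2r); roundness is `4 * pi * area / perimeter^2`
#' with a Crofton-corrected perimeter, clipped to \[0, 1\]. A single-pixel
#' mask degenerates to width = length = `pixel_size` and roundness 1.
#'
#' @param roi A `nucleus_roi`.
#' @param pixel_size Pixel edge length in micrometres.
#' @return Named numeric vector of length 4 in catalog order.
#' @export
basic_morphology <- function(roi, pixel_size = 1) {
  px <- roi$pixels
  n <- nrow(px)
  if (n == 0) stop("empty ROI mask", call. = FALSE)
  area_um2 <- n * pixel_size^2
  if (n == 1) {
    return(c("Nucleus Area" = area_um2, "Nucleus Roundness" = 1,
             "Nucleus Width" = pixel_size, "Nucleus Length" = pixel_size))
  }
  r <- px[, 1] - mean(px[, 1]); c_ <- px[, 2] - mean(px[, 2])
  cov <- matrix(c(mean(r^2), mean(r * c_), mean(r * c_), mean(c_^2)), 2, 2)
  ev <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0))
  len <- 4 * sqrt(ev[2]) * pixel_size
  wid <- 4 * sqrt(ev[1]) * pixel_size
  bb <- roi$bbox
  mask <- matrix(FALSE, bb[3] - bb[1] + 1, bb[4] - bb[2] + 1)
  mask[cbind(px[, 1] - bb[1] + 1, px[, 2] - bb[2] + 1)] <- TRUE
  per <- mask_perimeter(mask)
  round_ <- if (per > 0) clamp(4 * pi * n / per^2, 0, 1) else 1
  c("Nucleus Area" = area_um2, "Nucleus Roundness" = round_,
    "Nucleus Width" = wid, "Nucleus Length" = len)
}

#' Haralick co-occurrence features of one nucleus
#'
#' Pixels in the ROI are quantized to 32 grey levels between the ROI
#' minimum and maximum; a symmetric grey-level co-occurrence matrix at
#' distance 1 is accumulated over the four axis-aligned directions (each
#' horizontal and vertical neighbour pair counted in both orders),
#' counting only pixel pairs that both lie inside the ROI, and normalized
#' to sum 1. Returns the four co-occurrence statistics: contrast,
#' correlation, homogeneity (inverse difference moment), and sum variance.
#' A constant ROI (or one with no within-ROI pixel pairs) takes the
#' degenerate values contrast 0, correlation 0, homogeneity 1, sum
#' variance 0.
#'
#' @param roi A `nucleus_roi`.
#' @param dna Numeric matrix (DNA channel).
#' @param n_levels Number of quantization levels (default 32).
#' @return Named numeric vector of length 4 in catalog order.
#' @export
haralick_features <- function(roi, dna, n_levels = 32) {
  px <- roi$pixels
  if (nrow(px) == 0) stop("empty ROI mask", call. = FALSE)
  degenerate <- c("Nucleus Haralick Contrast" = 0,
                  "Nucleus Haralick Correlation" = 0,
                  "Nucleus Haralick Homogeneity" = 1,
                  "Nucleus Haralick Sum Variance" = 0)
  v <- dna[px]
  rng <- max(v) - min(v)
  if (rng == 0) return(degenerate)
  lev <- pmin(floor((v - min(v)) / rng * n_levels), n_levels - 1)
  bb <- roi$bbox
  h <- bb[3] - bb[1] + 1; w <- bb[4] - bb[2] + 1
  lm <- matrix(NA_integer_, h, w)
  lm[cbind(px[, 1] - bb[1] + 1, px[, 2] - bb[2] + 1)] <- as.integer(lev)
  counts <- numeric(n_levels * n_levels)
  add_pairs <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(invisible())
    code <- a[ok] * n_levels + b[ok] + 1
    tab <- tabulate(code, nbins = n_levels * n_levels)
    counts <<- counts + tab
    code2 <- b[ok] * n_levels + a[ok] + 1  # symmetric
    counts <<- counts + tabulate(code2, nbins = n_levels * n_levels)
    invisible()
  }
  if (w > 1) add_pairs(lm[, -w], lm[, -1])   # east (+ west via symmetry)
  if (h > 1) add_pairs(lm[-h, ], lm[-1, ])   # south (+ north via symmetry)
  if (sum(counts) == 0) return(degenerate)
  p <- matrix(counts / sum(counts), n_levels, n_levels, byrow = TRUE)
  i <- row(p) - 1; j <- col(p) - 1
  contrast <- sum(p * (i - j)^2)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  sd_i <- sqrt(sum(p * (i - mu_i)^2)); sd_j <- sqrt(sum(p * (j - mu_j)^2))
  correlation <- if (sd_i == 0 || sd_j == 0) 0 else {
    sum(p * (i - mu_i) * (j - mu_j)) / (sd_i * sd_j)
  }
  homogeneity <- sum(p / (1 + (i - j)^2))
  ks <- i + j
  p_sum <- vapply(0:(2 * n_levels - 2), function(k) sum(p[ks == k]), numeric(1))
  sum_avg <- sum((0:(2 * n_levels - 2)) * p_sum)
  sum_var <- sum(((0:(2 * n_levels - 2)) - sum_avg)^2 * p_sum)
  c("Nucleus Haralick Contrast" = contrast,
    "Nucleus Haralick Correlation" = correlation,
    "Nucleus Haralick Homogeneity" = homogeneity,
    "Nucleus Haralick Sum Variance" = sum_var)
}
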