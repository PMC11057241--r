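# Count lattice points of the bounding grid of `pts` that fall inside the
# convex hull of `pts` (boundary included). Used for threshold compactness.
pixels_in_hull <- function(pts) {
  n <- nrow(pts)
  if (n <= 2) return(n)
  hull <- grDevices::chull(pts[, 2], pts[, 1])  # x = col, y = row
  if (length(hull) <= 2) return(n)
  hx <- pts[hull, 2]; hy <- pts[hull, 1]
  rows <- min(pts[, 1]):max(pts[, 1])
  cols <- min(pts[, 2]):max(pts[, 2])
  gx <- rep(cols, each = length(rows))
  gy <- rep(rows, times = length(cols))
  inside <- rep(TRUE, length(gx))
  nh <- length(hull)
  # chull returns vertices clockwise in (x, y); test each half-plane
  for (k in seq_len(nh)) {
    k2 <- if (k == nh) 1L else k + 1L
    crossp <- (hx[k2] - hx[k]) * (gy - hy[k]) - (hy[k2] - hy[k]) * (gx - hx[k])
    inside <- inside & (crossp <= 1e-9)
    if (!any(inside)) break
  }
  if (!any(inside)) {
    # orientation was counter-clockwise; flip the test
    inside <- rep(TRUE, length(gx))
    for (k in seq_len(nh)) {
      k2 <- if (k == nh) 1L else k + 1L
      crossp <- (hx[k2] - hx[k]) * (gy - hy[k]) - (hy[k2] - hy[k]) * (gx - hx[k])
      inside <- inside & (crossp >= -1e-9)
    }
  }
  sum(inside)
}

# Distance of every ROI pixel to the mask border (distance transform of the
# cropped mask; pixels on the outline have distance 1).
roi_border_distance <- function(roi) {
  bb <- roi$bbox
  h <- bb[3] - bb[1] + 1; w <- bb[4] - bb[2] + 1
  mask <- matrix(0, h + 2, w + 2)
  mask[cbind(roi$pixels[, 1] - bb[1] + 2, roi$pixels[, 2] - bb[2] + 2)] <- 1
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask)))
  dm[cbind(roi$pixels[, 1] - bb[1] + 2, roi$pixels[, 2] - bb[2] + 2)]
}

#' STAR morphology properties of one nucleus
#'
#' The 23 intensity-weighted shape descriptors, computed on an image
#' variant (the raw DNA channel or one SER filter response). With `w_i`
#' the intensity of mask pixel `i` and `r_i`, `theta_i` its polar
#' coordinates about the intensity-weighted centroid:
#'
#' * symmetry(k), k = 1..8: `|sum_i w_i exp(i k theta_i)| / sum_i w_i`
#'   (0 when the total weight is 0) — angular Fourier moments; all near 0
#'   for circularly symmetric intensity.
#' * threshold compactness at t in 30..70%: area of the pixel set with
#'   `w >= t * max(w)` divided by the pixel area of that set's convex
#'   hull; 1 for sets of 2 pixels or fewer.
#' * axial: `sqrt(lmin)`, `sqrt(lmax)` of the intensity-weighted second-
#'   moment matrix, anisotropy `(lmax - lmin) / (lmax + lmin)` (0 when
#'   both are 0) and ratio `sqrt(lmin / lmax)` (1 when `lmax` is 0).
#' * radial: radial mean `sum w r / sum w`; radial relative deviation
#'   (intensity-weighted SD of r over the radial mean; 0 when the mean is
#'   0); radial mean over the equivalent radius `sqrt(area / pi)`; and the
#'   fraction of total intensity within half the equivalent radius.
#' * profile: Pearson correlation between `w` and the distance to the mask
#'   border (0 if either is constant), and the mean intensity in the outer
#'   border band (lowest quartile of border distance) over the mean
#'   elsewhere (1 for 0/0).
#'
#' @param roi A `nucleus_roi`.
#' @param img Numeric matrix: the image variant.
#' @param border_dist Optional precomputed [roi_border_distance()] values.
#' @return Named numeric vector of length 23 (names without the variant
#'   suffix), always finite.
#' @export
star_properties <- function(roi, img, border_dist = NULL) {
  px <- roi$pixels
  n <- nrow(px)
  if (n == 0) stop("empty ROI mask", call. = FALSE)
  w <- pmax(img[px], 0)
  W <- sum(w)
  out <- numeric(23)
  names(out) <- star_property_names()
  # centroid: intensity-weighted, geometric when there is no intensity
  if (W > 0) {
    rc <- sum(w * px[, 1]) / W; cc <- sum(w * px[, 2]) / W
  } else {
    rc <- mean(px[, 1]); cc <- mean(px[, 2])
  }
  dy <- px[, 1] - rc; dx <- px[, 2] - cc
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  for (k in 1:8) {
    out[k] <- if (W == 0) 0 else {
      sqrt(sum(w * cos(k * th))^2 + sum(w * sin(k * th))^2) / W
    }
  }
  mx <- max(w)
  thr_t <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  for (t in seq_along(thr_t)) {
    sel <- if (mx == 0) rep(TRUE, n) else w >= thr_t[t] * mx
    pts <- px[sel, , drop = FALSE]
    out[8 + t] <- if (nrow(pts) <= 2) 1 else nrow(pts) / pixels_in_hull(pts)
  }
  if (W > 0) {
    sxx <- sum(w * dx^2) / W; syy <- sum(w * dy^2) / W; sxy <- sum(w * dx * dy) / W
    d <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
    lmax <- pmax((sxx + syy + d) / 2, 0); lmin <- pmax((sxx + syy - d) / 2, 0)
  } else {
    lmax <- 0; lmin <- 0
  }
  out[14] <- sqrt(lmin)
  out[15] <- sqrt(lmax)
  out[16] <- if (lmax + lmin == 0) 0 else (lmax - lmin) / (lmax + lmin)
  out[17] <- if (lmax == 0) 1 else sqrt(lmin / lmax)
  req <- sqrt(n / pi)
  rm_ <- if (W == 0) 0 else sum(w * r) / W
  out[18] <- rm_
  out[19] <- if (rm_ == 0) 0 else sqrt(sum(w * (r - rm_)^2) / W) / rm_
  out[20] <- rm_ / req
  out[21] <- if (W == 0) 0 else sum(w[r <= req / 2]) / W
  bd <- border_dist %||% roi_border_distance(roi)
  out[22] <- if (stats::sd(w) == 0 || stats::sd(bd) == 0) 0 else stats::cor(w, bd)
  band <- bd <= stats::quantile(bd, 0.25)
  m1 <- if (any(band)) mean(w[band]) else 0
  m2 <- if (any(!band)) mean(w[!band]) else 0
  out[23] <- if (m2 > 0) m1 / m2 else if (m1 == 0) 1 else m1
  out
}
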