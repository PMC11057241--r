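gaussian_smooth <- function(img, sigma) {
  # default kernel radius is 2*ceil(3*sigma)+1; cap it so small images work
  radius <- 2 * ceiling(3 * sigma) + 1
  max_r <- min(dim(img)) - (1 - min(dim(img)) %% 2)  # largest odd <= min dim
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = min(radius, max_r)))
}

# Central-difference partial derivatives with replicated borders.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- clamp(seq_len(h) + dr, 1, h)
  ci <- clamp(seq_len(w) + dc, 1, w)
  m[ri, ci, drop = FALSE]
}

#' SER texture filter bank
#'
#' Computes the eight "spots, edges, ridges" pattern responses at one
#' scale. With `I_s` the Gaussian-smoothed image at scale `sigma`,
#' `l1 <= l2` the eigenvalues of the scale-normalized Hessian
#' (`sigma^2 * H`), `g` the scale-normalized gradient magnitude
#' (`sigma * |grad I_s|`), and `I_bg` a coarse background (Gaussian at
#' `4 * sigma`):
#' spot `= sqrt((-l1)+ * (-l2)+)`, hole `= sqrt(l1+ * l2+)`,
#' ridge `= (-l1)+ - (-l2)+`, valley `= l2+ - l1+`,
#' saddle `= sqrt((-l1)+ * l2+)`, edge `= g`,
#' bright `= (I_s - I_bg)+`, dark `= (I_bg - I_s)+`,
#' where `x+ = max(x, 0)`. All responses are non-negative and identically
#' zero on a constant image.
#'
#' @param dna Numeric matrix.
#' @param sigma Filter scale in px (> 0).
#' @return Named list of 8 response matrices in catalog order
#'   (Spot, Hole, Ridge, Valley, Saddle, Edge, Bright, Dark).
#' @export
ser_filter_bank <- function(dna, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  if (!is.matrix(dna)) stop("`dna` must be a matrix", call. = FALSE)
  s <- gaussian_smooth(dna, sigma)
  gx <- (shift_mat(s, 0, 1) - shift_mat(s, 0, -1)) / 2
  gy <- (shift_mat(s, 1, 0) - shift_mat(s, -1, 0)) / 2
  fxx <- shift_mat(s, 0, 1) - 2 * s + shift_mat(s, 0, -1)
  fyy <- shift_mat(s, 1, 0) - 2 * s + shift_mat(s, -1, 0)
  fxy <- (shift_mat(s, 1, 1) - shift_mat(s, 1, -1) -
            shift_mat(s, -1, 1) + shift_mat(s, -1, -1)) / 4
  sc <- sigma^2
  tr <- sc * (fxx + fyy)
  det_d <- sc * sqrt(pmax((fxx - fyy)^2 + 4 * fxy^2, 0))
  l1 <- (tr - det_d) / 2  # l1 <= l2
  l2 <- (tr + det_d) / 2
  n1 <- pmax(-l1, 0); n2 <- pmax(-l2, 0)
  p1 <- pmax(l1, 0); p2 <- pmax(l2, 0)
  bg <- gaussian_smooth(dna, 4 * sigma)
  list(
    Spot = sqrt(n1 * n2),
    Hole = sqrt(p1 * p2),
    Ridge = n1 - n2,
    Valley = p2 - p1,
    Saddle = sqrt(n1 * p2),
    Edge = sigma * sqrt(gx^2 + gy^2),
    Bright = pmax(s - bg, 0),
    Dark = pmax(bg - s, 0)
  )
}

#' Per-nucleus SER features at one scale
#'
#' The ROI reduction of each filter response: mean squared response over
#' the ROI divided by the squared ROI mean of the input image (0 when that
#' mean is 0), making the features invariant to global intensity scaling.
#'
#' @param roi A `nucleus_roi`.
#' @param bank Output of [ser_filter_bank()].
#' @param dna The image the bank was computed from.
#' @param scale Scale tag used in the feature names.
#' @return Named numeric vector of 8 features.
#' @export
ser_features <- function(roi, bank, dna, scale = 1) {
  px <- roi$pixels
  m <- mean(dna[px])
  vals <- vapply(bank, function(resp) {
    if (m == 0) 0 else mean(resp[px]^2) / m^2
  }, numeric(1))
  names(vals) <- sprintf("Nucleus SER %s %dpx", names(bank), scale)
  vals
}
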