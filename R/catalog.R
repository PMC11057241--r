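#' Names of the eight SER texture filters
#'
#' The "spots, edges, ridges" family: eight per-pixel pattern detectors
#' built from the eigenvalues of the scale-normalized Hessian, the gradient
#' magnitude, and a coarse background difference.
#'
#' @return Character vector of length 8 in catalog order.
#' @export
ser_filter_names <- function() {
  c("Spot", "Hole", "Ridge", "Valley", "Saddle", "Edge", "Bright", "Dark")
}

#' Names of the 23 STAR morphology properties
#'
#' Intensity-weighted shape descriptors computed per nucleus: 8 angular
#' symmetry moments, 5 threshold-compactness values, 4 axial (second moment)
#' descriptors, 4 radial descriptors, and 2 intensity-profile descriptors.
#'
#' @return Character vector of length 23 in catalog order.
#' @export
star_property_names <- function() {
  c(sprintf("Symmetry %02d", 1:8),
    sprintf("Threshold Compactness %d%%", c(30, 40, 50, 60, 70)),
    "Axial Small Length", "Axial Length", "Axial Anisotropy", "Axial Ratio",
    "Radial Mean", "Radial Relative Deviation", "Radial Mean Normalized",
    "Radial Inner Intensity Fraction",
    "Profile Correlation", "Profile Border Ratio")
}

#' The frozen 240-feature catalog
#'
#' Defines the name, family, image variant and scale of every feature the
#' pipeline computes from the DNA channel of a segmented nucleus, in a fixed
#' order: 9 intensity properties, 4 basic morphology properties, 16 SER
#' texture features (8 filters x 2 scales), 4 Haralick co-occurrence
#' statistics, and 207 STAR properties (23 properties x 9 image variants:
#' the raw DNA channel plus the 8 SER filter responses at scale 1 px).
#'
#' @return A data.frame with 240 rows and columns `name`, `family`,
#'   `variant` (image variant a STAR property is computed on; `"raw"`
#'   otherwise), and `scale` (filter scale in px; `NA` where not
#'   applicable).
#' @examples
#' cat240 <- feature_catalog()
#' nrow(cat240)     # 240
#' table(cat240$family)
#' @export
feature_catalog <- function() {
  intensity <- paste("Intensity Nucleus",
                     c("Mean", "SD", "Median", "Max", "Min", "Sum", "CV",
                       "Quantile50", "Contrast"))
  morph <- paste("Nucleus", c("Area", "Roundness", "Width", "Length"))
  sers <- ser_filter_names()
  ser <- c(sprintf("Nucleus SER %s 1px", sers), sprintf("Nucleus SER %s 2px", sers))
  haralick <- paste("Nucleus Haralick",
                    c("Contrast", "Correlation", "Homogeneity", "Sum Variance"))
  props <- star_property_names()
  variants <- c("raw", paste0("SER-", sers))
  star <- unlist(lapply(variants, function(v) {
    if (v == "raw") paste("Nucleus", props) else paste("Nucleus", props, v)
  }))
  data.frame(
    name = c(intensity, morph, ser, haralick, star),
    family = c(rep("intensity", 9), rep("basic_morphology", 4),
               rep("SER", 16), rep("haralick", 4), rep("STAR", 207)),
    variant = c(rep("raw", 9 + 4), rep("raw", 16), rep("raw", 4),
                rep(variants, each = 23)),
    scale = c(rep(NA_real_, 9 + 4), rep(c(1, 2), each = 8),
              rep(NA_real_, 4), rep(NA_real_, 207)),
    stringsAsFactors = FALSE
  )
}

#' Write the feature catalog as JSON
#'
#' @param path Output file path.
#' @param catalog Catalog data.frame, by default [feature_catalog()].
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(path, catalog = feature_catalog()) {
  jsonlite::write_json(catalog, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
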