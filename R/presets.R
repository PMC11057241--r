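#' Fucci gating configuration
#'
#' Threshold rules that translate the mean red (mKO2/mCherry-hCdt1) and
#' green (mAG-hGeminin) reporter intensities of a nucleus into one of four
#' classes: G1 (red on, green off), early S (both on), S/G2/M (green on,
#' red off) and double negative (both off). The built-in thresholds are the
#' published gate positions for the two cell lines: HeLa red >= 700 /
#' green >= 2500; MCF7 red >= 150 / green >= 300 (intensity counts).
#' Nuclei whose DNA-channel coefficient of variation exceeds
#' `cv_exclusion_pct` are flagged apoptotic and excluded when
#' `cv_exclusion_enabled`; this filter addresses dead-cell contamination
#' observed in MCF7 cultures and is therefore enabled for MCF7 only by
#' default.
#'
#' @param cell_line `"HeLa"` or `"MCF7"`; sets default thresholds.
#' @param red_threshold,green_threshold Gate positions in intensity counts.
#' @param cv_exclusion_pct CV threshold in percent (default 70).
#' @param cv_exclusion_enabled Whether the apoptotic CV filter is applied.
#' @return An object of class `fucci_gating_config`.
#' @examples
#' fucci_gating_config("HeLa")
#' fucci_gating_config("MCF7")
#' @export
fucci_gating_config <- function(cell_line = c("HeLa", "MCF7"),
                                red_threshold = NULL,
                                green_threshold = NULL,
                                cv_exclusion_pct = 70,
                                cv_exclusion_enabled = NULL) {
  cell_line <- match.arg(cell_line)
  defaults <- switch(cell_line,
    HeLa = list(red = 700, green = 2500, cv_on = FALSE),
    MCF7 = list(red = 150, green = 300, cv_on = TRUE)
  )
  red_threshold <- red_threshold %||% defaults$red
  green_threshold <- green_threshold %||% defaults$green
  cv_exclusion_enabled <- cv_exclusion_enabled %||% defaults$cv_on
  stopifnot(red_threshold > 0, green_threshold > 0, cv_exclusion_pct > 0)
  structure(
    list(cell_line = cell_line,
         red_threshold = red_threshold,
         green_threshold = green_threshold,
         cv_exclusion_pct = cv_exclusion_pct,
         cv_exclusion_enabled = isTRUE(cv_exclusion_enabled)),
    class = "fucci_gating_config"
  )
}

#' Define one experimental condition for the simulator
#'
#' A condition is one (cell line, drug, concentration) well type together
#' with the cell-cycle distribution it induces: a probability vector over
#' the four gated classes plus an apoptotic fraction.
#'
#' @param cell_line `"HeLa"` or `"MCF7"`.
#' @param drug Drug name (`"control"` for vehicle).
#' @param concentration Molar concentration (0 for control).
#' @param phase_probs Numeric 4-vector of probabilities over
#'   `c("G1","earlyS","SG2M","DN")`; must sum to 1.
#' @param apoptotic_frac Probability that a cell is apoptotic (fragmented
#'   nucleus) rather than in one of the four classes.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(cell_line, drug, concentration, phase_probs,
                             apoptotic_frac = 0) {
  phase_probs <- as.numeric(phase_probs)
  if (length(phase_probs) != 4 || any(phase_probs < 0) ||
      abs(sum(phase_probs) - 1) > 1e-9) {
    stop("`phase_probs` must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (apoptotic_frac < 0 || apoptotic_frac > 1) {
    stop("`apoptotic_frac` must be in [0, 1]", call. = FALSE)
  }
  if (concentration < 0) stop("`concentration` must be >= 0", call. = FALSE)
  names(phase_probs) <- phase_levels()
  structure(
    list(cell_line = match.arg(cell_line, c("HeLa", "MCF7")),
         drug = drug, concentration = concentration,
         phase_probs = phase_probs, apoptotic_frac = apoptotic_frac),
    class = "condition_preset"
  )
}

#' Built-in condition presets
#'
#' Control plus one high-dose preset per drug for each cell line. The
#' presets are qualitative: cytotoxic drugs (5-FU at 10 uM, SN-38 at
#' 0.1 uM) push HeLa populations toward S/G2/M; the PI3K inhibitor ZSTK474
#' (1 uM) accumulates MCF7 cells in G1 but leaves HeLa largely unchanged;
#' staurosporine (0.1 uM) mainly raises the apoptotic fraction; the MEK
#' inhibitor selumetinib (1 uM) causes a mild G1 shift. Exact fractions are
#' free simulator parameters, not measured values.
#'
#' @param cell_line `"HeLa"` or `"MCF7"`.
#' @return Named list of [condition_preset()] objects; the first is the
#'   control.
#' @examples
#' names(condition_presets("HeLa"))
#' @export
condition_presets <- function(cell_line = c("HeLa", "MCF7")) {
  cell_line <- match.arg(cell_line)
  p <- function(drug, conc, probs, apo) {
    condition_preset(cell_line, drug, conc, probs, apo)
  }
  if (cell_line == "HeLa") {
    list(
      control       = p("control",       0,     c(0.55, 0.10, 0.30, 0.05), 0.02),
      `5-FU`        = p("5-FU",          1e-5,  c(0.22, 0.10, 0.63, 0.05), 0.05),
      `SN-38`       = p("SN-38",         1e-7,  c(0.18, 0.10, 0.67, 0.05), 0.05),
      selumetinib   = p("selumetinib",   1e-6,  c(0.62, 0.08, 0.25, 0.05), 0.03),
      staurosporine = p("staurosporine", 1e-7,  c(0.48, 0.09, 0.33, 0.10), 0.25),
      ZSTK474       = p("ZSTK474",       1e-6,  c(0.56, 0.10, 0.29, 0.05), 0.03)
    )
  } else {
    list(
      control       = p("control",       0,     c(0.58, 0.08, 0.28, 0.06), 0.06),
      `5-FU`        = p("5-FU",          1e-5,  c(0.52, 0.10, 0.32, 0.06), 0.10),
      `SN-38`       = p("SN-38",         1e-7,  c(0.50, 0.10, 0.34, 0.06), 0.10),
      selumetinib   = p("selumetinib",   1e-6,  c(0.64, 0.07, 0.23, 0.06), 0.06),
      staurosporine = p("staurosporine", 1e-7,  c(0.52, 0.08, 0.30, 0.10), 0.28),
      ZSTK474       = p("ZSTK474",       1e-6,  c(0.80, 0.04, 0.10, 0.06), 0.06)
    )
  }
}
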