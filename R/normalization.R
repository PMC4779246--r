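#' Molar extinction coefficient of resorufin
#'
#' Used by the Amplex-red H2O2 assay to convert background-corrected
#' absorbance into molar H2O2 concentration (1:1 resorufin:H2O2
#' stoichiometry), in L mol-1 cm-1.
#' @export
resorufin_extinction <- 54000

#' Normalize an absorbance reading to percent of the positive control
#'
#' LDH and GLU release are read photometrically at 405 nm, corrected for the
#' absorbance of the matching cell-free particle control (particles adsorb
#' and scatter light), and expressed relative to the full-lysis positive
#' control (NR8383 cells lysed with 0.1 % Triton X-100, set to 100 %).
#' Slightly negative values can occur after background correction and are
#' retained so the downstream statistics see unbiased noise.
#'
#' @param od_sample Sample absorbance.
#' @param od_cell_free_particle_control Absorbance of the cell-free particle
#'   control at the same concentration.
#' @param pc_value Background-corrected absorbance of the positive control;
#'   must be positive.
#' @return Percent of positive control (vectorized).
#' @export
#' @examples
#' percent_of_pc(0.6, 0.1, 1.0) # 50
percent_of_pc <- function(od_sample, od_cell_free_particle_control, pc_value) {
  if (any(!is.finite(pc_value)) || any(pc_value <= 0)) {
    abort("Positive-control absorbance must be > 0 (invalid plate).",
          class = "amtox_error_plate")
  }
  100 * (od_sample - od_cell_free_particle_control) / pc_value
}

#' Express a crystal-violet reading as TNF-alpha standard-referenced lysis
#'
#' The TNF-alpha bioassay measures lysis of actinomycin-D-sensitized L929
#' fibroblasts by crystal violet staining: absorbance at 570 nm decreases as
#' cells lyse. Readings are rescaled linearly between two anchors: the
#' non-treated medium control (0 % lysis) and the 1000 pg/mL TNF-alpha
#' standard (100 %). Values beyond either anchor are allowed.
#'
#' @param od_treated_l929 Absorbance of L929 cells exposed to the supernatant.
#' @param od_medium_control Absorbance of the non-treated medium control.
#' @param od_standard_1000pg Absorbance at the 1000 pg/mL TNF-alpha standard;
#'   must be below the medium control.
#' @return Percent of the 1000 pg/mL standard (vectorized).
#' @export
#' @examples
#' tnf_lysis_percent(0.6, 0.8, 0.4) # 50
tnf_lysis_percent <- function(od_treated_l929, od_medium_control, od_standard_1000pg) {
  if (any(od_medium_control <= od_standard_1000pg)) {
    abort("Medium-control OD must exceed the 1000 pg/mL standard OD (invalid standard).",
          class = "amtox_error_standard")
  }
  100 * (od_medium_control - od_treated_l929) /
    (od_medium_control - od_standard_1000pg)
}

#' Convert Amplex-red absorbance to H2O2 concentration
#'
#' Resorufin absorbance is read at 570 nm against a 620 nm reference,
#' corrected for the cell-free particle control, and converted to micromolar
#' H2O2 with the Beer-Lambert law and the resorufin extinction coefficient
#' (54,000 L mol-1 cm-1). The optical path length in a 96-well plate depends
#' on the filling volume; the default of 0.6 cm corresponds to 200 uL in a
#' standard flat-bottom well.
#'
#' @param od_570 Absorbance at 570 nm.
#' @param od_620 Reference absorbance at 620 nm (default 0).
#' @param od_cell_free_control Background absorbance of the cell-free particle
#'   control (default 0).
#' @param path_length_cm Optical path length in cm; must be positive.
#' @return H2O2 concentration in uM (vectorized).
#' @export
#' @examples
#' h2o2_concentration(0.054, path_length_cm = 1) # 1 uM
h2o2_concentration <- function(od_570, od_620 = 0, od_cell_free_control = 0,
                               path_length_cm = 0.6) {
  if (any(!is.finite(path_length_cm)) || any(path_length_cm <= 0)) {
    abort("`path_length_cm` must be > 0.", class = "amtox_error_argument")
  }
  corrected <- (od_570 - od_620) - od_cell_free_control
  corrected / (resorufin_extinction * path_length_cm) * 1e6
}

#' Reporting transform: H2O2 as percent of the zymosan positive control
#'
#' H2O2 is analysed in uM; summary tables report it relative to the zymosan
#' positive control. This is a display transform only.
#'
#' @param conc_um H2O2 concentration (uM).
#' @param zymosan_um Concentration measured for the zymosan control (uM, > 0).
#' @return Percent of positive control.
#' @export
h2o2_percent_of_pc <- function(conc_um, zymosan_um) {
  if (any(zymosan_um <= 0)) {
    abort("Zymosan control concentration must be > 0.", class = "amtox_error_plate")
  }
  100 * conc_um / zymosan_um
}
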