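#' Round half away from zero
#'
#' Published surface-area doses are rounded half-up to whole mm2/mL (337.5
#' prints as 338), unlike R's round-half-to-even. Classification always uses
#' the unrounded value; this helper is for reporting parity only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Convert a mass concentration to a surface-area dose
#'
#' Multiplies the applied mass concentration (ug/mL) by the material's BET
#' specific surface area (m2/g). Because 1 m2/g equals 1 mm2/ug, the product
#' is numerically the particle surface area per medium volume in mm2/mL, the
#' dose metric on which the in vitro classification threshold is defined.
#'
#' @param concentration_ug_per_ml Mass concentration(s), ug/mL (>= 0).
#' @param bet_m2_per_g BET specific surface area, m2/g (>= 0).
#' @param reported If `TRUE`, round half-up to integer mm2/mL as in published
#'   tables. Default `FALSE` (classification uses unrounded values).
#' @return Surface-area dose(s) in mm2/mL.
#' @export
#' @examples
#' surface_dose(90, 47)                   # 4230
#' surface_dose(22.5, 15, reported = TRUE) # 338
surface_dose <- function(concentration_ug_per_ml, bet_m2_per_g, reported = FALSE) {
  if (any(concentration_ug_per_ml < 0, na.rm = TRUE) ||
      any(bet_m2_per_g < 0, na.rm = TRUE)) {
    abort("Concentrations and BET areas must be non-negative.",
          class = "amtox_error_argument")
  }
  out <- concentration_ug_per_ml * bet_m2_per_g
  if (reported) round_half_up(out) else out
}

#' Culture geometry of the NR8383 assay
#'
#' Bundles the physical constants that tie the per-cell particle-surface
#' threshold to its per-volume and per-area equivalents: 3 x 10^5 cells
#' gathering particles at the bottom of a 96-well plate well, 200 uL medium,
#' 1/3 cm2 growth area, and a threshold of 4000 um2 particle surface per
#' cell. With these defaults the threshold is 1200 mm2 per well, i.e.
#' 6000 mm2/mL and 3600 mm2/cm2.
#'
#' @param cells_per_well Number of cells per well.
#' @param well_volume_ml Medium volume per well, mL.
#' @param well_growth_area_cm2 Growth area per well, cm2.
#' @param cell_threshold_um2 Particle surface threshold per cell, um2.
#' @return An object of class `am_geometry`.
#' @export
#' @examples
#' volume_threshold(culture_geometry()) # 6000
culture_geometry <- function(cells_per_well = 3e5, well_volume_ml = 0.2,
                             well_growth_area_cm2 = 1 / 3,
                             cell_threshold_um2 = 4000) {
  vals <- c(cells_per_well, well_volume_ml, well_growth_area_cm2, cell_threshold_um2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All culture geometry parameters must be positive.",
          class = "amtox_error_argument")
  }
  structure(
    list(
      cells_per_well = cells_per_well,
      well_volume_ml = well_volume_ml,
      well_growth_area_cm2 = well_growth_area_cm2,
      cell_threshold_um2 = cell_threshold_um2
    ),
    class = "am_geometry"
  )
}

#' @export
print.am_geometry <- function(x, ...) {
  cat("NR8383 culture geometry\n")
  cat(sprintf("  cells/well: %g, volume: %g mL, growth area: %g cm2\n",
              x$cells_per_well, x$well_volume_ml, x$well_growth_area_cm2))
  cat(sprintf("  per-cell threshold: %g um2 -> %g mm2/mL, %g mm2/cm2\n",
              x$cell_threshold_um2, volume_threshold(x), area_threshold(x)))
  invisible(x)
}

# um2/well -> mm2/well conversion factor
UM2_PER_MM2 <- 1e6

#' Surface-area classification thresholds implied by the culture geometry
#'
#' `volume_threshold()` expresses the per-cell threshold as particle surface
#' per medium volume (mm2/mL); `area_threshold()` expresses it per cell
#' culture growth area (mm2/cm2). With the default geometry these are 6000
#' mm2/mL and 3600 mm2/cm2.
#'
#' @param geometry An [culture_geometry()] object.
#' @return Threshold in mm2/mL (`volume_threshold`) or mm2/cm2
#'   (`area_threshold`).
#' @export
volume_threshold <- function(geometry = culture_geometry()) {
  stopifnot(inherits(geometry, "am_geometry"))
  geometry$cell_threshold_um2 * geometry$cells_per_well / UM2_PER_MM2 /
    geometry$well_volume_ml
}

#' @rdname volume_threshold
#' @export
area_threshold <- function(geometry = culture_geometry()) {
  stopifnot(inherits(geometry, "am_geometry"))
  geometry$cell_threshold_um2 * geometry$cells_per_well / UM2_PER_MM2 /
    geometry$well_growth_area_cm2
}

#' Mass-per-area equivalent of the classification threshold for one material
#'
#' Divides the per-area surface threshold (mm2/cm2) by the material's BET
#' area (1 m2/g = 1 mm2/ug) to give the mass loading per culture area at
#' which that material reaches the threshold. With the default geometry this
#' is 240 ug/cm2 at BET 15 m2/g (ZnO-like) and 18 ug/cm2 at 200 m2/g
#' (colloidal silica-like).
#'
#' @param bet_m2_per_g BET specific surface area, m2/g (> 0).
#' @param geometry An [culture_geometry()] object.
#' @return Threshold-equivalent mass per culture area, ug/cm2.
#' @export
#' @examples
#' mass_threshold_per_area(15) # 240
mass_threshold_per_area <- function(bet_m2_per_g, geometry = culture_geometry()) {
  if (any(!is.finite(bet_m2_per_g)) || any(bet_m2_per_g <= 0)) {
    abort("`bet_m2_per_g` must be > 0.", class = "amtox_error_argument")
  }
  area_threshold(geometry) / bet_m2_per_g
}

#' Rat lung model for extrapolating the per-cell threshold
#'
#' The per-cell threshold can be scaled to the whole rat lung via the total
#' alveolar macrophage population (1-2 x 10^7 in healthy rats) and a lung
#' mass of about 1 g, giving a lung surface-burden threshold of 0.04-0.08 m2
#' (equivalently m2/g lung tissue).
#'
#' @param ams_per_lung Length-2 numeric range of alveolar macrophages per
#'   lung (lower, upper).
#' @param lung_mass_g Lung mass in grams.
#' @return An object of class `am_lung_model`.
#' @export
lung_model <- function(ams_per_lung = c(1e7, 2e7), lung_mass_g = 1) {
  if (length(ams_per_lung) != 2 || any(ams_per_lung <= 0) ||
      ams_per_lung[1] > ams_per_lung[2] || lung_mass_g <= 0) {
    abort("`ams_per_lung` must be a positive increasing range and `lung_mass_g` > 0.",
          class = "amtox_error_argument")
  }
  structure(list(ams_per_lung = ams_per_lung, lung_mass_g = lung_mass_g),
            class = "am_lung_model")
}

#' Lung-level surface and mass equivalents of the per-cell threshold
#'
#' `lung_surface_threshold()` multiplies the per-cell threshold (um2/cell) by
#' the macrophage population range, returning the lung surface-burden range
#' in m2 (0.04-0.08 m2 by default). `lung_mass_equivalent()` divides that
#' range by a material's BET area to give the corresponding lung mass burden
#' in mg (e.g. 0.2-0.4 mg at BET 200 m2/g).
#'
#' @param lung An [lung_model()] object.
#' @param cell_threshold_um2 Per-cell surface threshold, um2.
#' @param bet_m2_per_g BET specific surface area, m2/g (> 0).
#' @return A named numeric range (lower, upper) in m2 or mg.
#' @export
#' @examples
#' lung_surface_threshold()      # 0.04 0.08
#' lung_mass_equivalent(200)     # 0.2 0.4
lung_surface_threshold <- function(lung = lung_model(), cell_threshold_um2 = 4000) {
  stopifnot(inherits(lung, "am_lung_model"))
  um2 <- cell_threshold_um2 * lung$ams_per_lung
  out <- um2 / 1e12 # um2 -> m2
  names(out) <- c("lower", "upper")
  out
}

#' @rdname lung_surface_threshold
#' @export
lung_mass_equivalent <- function(bet_m2_per_g, lung = lung_model(),
                                 cell_threshold_um2 = 4000) {
  if (any(!is.finite(bet_m2_per_g)) || any(bet_m2_per_g <= 0)) {
    abort("`bet_m2_per_g` must be > 0.", class = "amtox_error_argument")
  }
  surface_m2 <- lung_surface_threshold(lung, cell_threshold_um2)
  surface_m2 / bet_m2_per_g * 1000 # g -> mg
}

#' Convert a NOAEC to its 5-day equivalent
#'
#' Short-term inhalation studies run for 5 exposure days; a 28-day sub-acute
#' NOAEC is converted to a 5-day equivalent by multiplying by four (four
#' consecutive 5-day exposure periods). 5-day records pass through unchanged
#' and bound qualifiers are preserved by the caller.
#'
#' @param noaec_mg_m3 NOAEC value(s), mg/m3.
#' @param exposure_days Exposure duration(s), 5 or 28.
#' @return 5-day-equivalent NOAEC(s), mg/m3.
#' @export
#' @examples
#' five_day_noaec(3, 28) # 12
five_day_noaec <- function(noaec_mg_m3, exposure_days) {
  if (!all(exposure_days %in% c(5, 28))) {
    abort("`exposure_days` must be 5 or 28.", class = "amtox_error_argument")
  }
  ifelse(exposure_days == 28, noaec_mg_m3 * 4, noaec_mg_m3)
}
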