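#' Assay endpoints and their reporting units
#'
#' The NR8383 AM assay records four endpoints per material: lactate
#' dehydrogenase release (LDH) and beta-glucuronidase release (GLU), both as
#' percent of the Triton X-100 full-lysis positive control; bioactive
#' TNF-alpha as percent L929 fibroblast lysis scaled to the 1000 pg/mL
#' standard; and extracellular H2O2, measured in micromolar and reported as
#' percent of the zymosan positive control.
#'
#' @return A tibble with columns `endpoint` and `unit`.
#' @export
#' @examples
#' am_endpoints()
am_endpoints <- function() {
  tibble::tibble(
    endpoint = c("LDH", "GLU", "TNF", "H2O2"),
    unit = c(
      "% of positive control",
      "% of positive control",
      "% of standard-referenced L929 lysis",
      "% of positive control (uM internally)"
    )
  )
}

fixture_dir <- function(fixture_set) {
  path <- system.file("extdata", fixture_set, package = "amtox")
  if (identical(path, "") || !dir.exists(path)) {
    abort(
      sprintf("Unknown fixture set '%s'.", fixture_set),
      class = "amtox_error_lookup"
    )
  }
  path
}

parse_series <- function(x, row) {
  out <- suppressWarnings(as.numeric(strsplit(x, ";", fixed = TRUE)[[1]]))
  if (anyNA(out) || length(out) < 2 || out[1] != 0 || any(diff(out) <= 0)) {
    abort(
      sprintf("Malformed concentration series in fixture row '%s'.", row),
      class = "amtox_error_parse"
    )
  }
  out
}

#' Load the packaged assay fixture tables
#'
#' Loads the material registry, the endpoint summary grid (mean and SD per
#' material, endpoint and concentration), the published per-endpoint in vitro
#' LOAEC table, and the rat short-term inhalation study (STIS) records for the
#' 20-material evaluation shipped with the package, and validates their
#' invariants (positive BET areas, strictly increasing concentration series
#' starting at 0, non-negative SDs).
#'
#' @param fixture_set Name of a packaged dataset. Currently `"wiemann2016"`.
#' @return A named list of tibbles:
#' \describe{
#'   \item{materials}{one row per material (22: 20 test materials plus the
#'     corundum and quartz DQ12 benchmarks), with BET surface area (m2/g),
#'     class, form, and the per-endpoint concentration series as a list-column
#'     `series` of named numeric vectors.}
#'   \item{summary}{the mean/SD summary grid, one row per material x endpoint
#'     x concentration, with the published significance flag.}
#'   \item{loaec}{the published mass-based in vitro LOAECs (ug/mL; NA where
#'     not significant) with the printed surface-area values (mm2/mL) where
#'     unambiguous, and a `determined` flag (FALSE for the one endpoint not
#'     measured).}
#'   \item{stis}{the STIS records: NOAEC (mg/m3) with bound qualifier
#'     (`exact`, `at_least`, `below`), LOAEC where recorded, exposure duration
#'     in days and the material role (`test` or `positive_control`).}
#' }
#' @export
#' @examples
#' fx <- am_fixture()
#' fx$materials
am_fixture <- function(fixture_set = "wiemann2016") {
  dir <- fixture_dir(fixture_set)

  materials <- readr::read_csv(
    file.path(dir, "materials.csv"),
    col_types = readr::cols(
      name = "c", material_class = "c", bet_m2_per_g = "d", form = "c",
      primary_particle_size_nm = "c", series_ldh = "c", series_glu = "c",
      series_tnf = "c", series_h2o2 = "c", notes = "c"
    ),
    na = "NA"
  )
  materials$series <- purrr::pmap(
    list(materials$series_ldh, materials$series_glu,
         materials$series_tnf, materials$series_h2o2, materials$name),
    function(l, g, t, h, nm) {
      list(LDH = parse_series(l, nm), GLU = parse_series(g, nm),
           TNF = parse_series(t, nm), H2O2 = parse_series(h, nm))
    }
  )
  materials <- dplyr::select(materials, -dplyr::starts_with("series_"))
  bad_bet <- !is.na(materials$bet_m2_per_g) & materials$bet_m2_per_g <= 0
  if (any(bad_bet)) {
    abort(
      sprintf("Non-positive BET area in fixture row '%s'.",
              materials$name[bad_bet][1]),
      class = "amtox_error_parse"
    )
  }

  summary <- readr::read_csv(
    file.path(dir, "table2_summary.csv"),
    col_types = readr::cols(
      material = "c", endpoint = "c", concentration_ug_per_ml = "d",
      mean = "d", sd = "d", significant = "l"
    )
  )
  if (any(summary$sd < 0) || !all(summary$endpoint %in% am_endpoints()$endpoint)) {
    abort("Malformed summary fixture (negative SD or unknown endpoint).",
          class = "amtox_error_parse")
  }

  loaec <- readr::read_csv(
    file.path(dir, "table3_loaec.csv"),
    col_types = readr::cols(
      material = "c", endpoint = "c", loaec_ug_per_ml = "d",
      mm2_printed = "d", determined = "l"
    ),
    na = "NA"
  )

  stis <- readr::read_csv(
    file.path(dir, "stis.csv"),
    col_types = readr::cols(
      material = "c", noaec_mg_m3 = "d", noaec_bound = "c", loaec_mg_m3 = "d",
      exposure_days = "i", role = "c", reference = "c"
    ),
    na = "NA"
  )
  if (!all(stis$noaec_bound %in% c("exact", "at_least", "below")) ||
      !all(stis$exposure_days %in% c(5L, 28L))) {
    abort("Malformed STIS fixture row.", class = "amtox_error_parse")
  }
  bad <- stis$noaec_bound == "exact" & !is.na(stis$loaec_mg_m3) &
    stis$loaec_mg_m3 <= stis$noaec_mg_m3
  if (any(bad)) {
    abort(
      sprintf("STIS fixture row '%s': LOAEC must exceed an exact NOAEC.",
              stis$material[bad][1]),
      class = "amtox_error_parse"
    )
  }

  list(materials = materials, summary = summary, loaec = loaec, stis = stis)
}

#' Moment-exact replicate values for one summary cell
#'
#' Reconstructs `n` replicate values whose sample mean and sample standard
#' deviation equal the given moments exactly, so that summary tables
#' (mean +/- SD) can drive the ANOVA/Dunnett stage. For `n = 3` the
#' construction is `{mean - sd, mean, mean + sd}`.
#'
#' @param mean,sd Target sample mean and sample standard deviation (`sd >= 0`).
#' @param n Number of replicates, at least 2.
#' @return A numeric vector of length `n`.
#' @export
#' @examples
#' moment_replicates(10, 2, 3) # 8 10 12
moment_replicates <- function(mean, sd, n = 3) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    abort("`n` must be an integer >= 2.", class = "amtox_error_argument")
  }
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    abort("`mean` must be finite and `sd` finite and non-negative.",
          class = "amtox_error_argument")
  }
  base <- seq_len(n)
  z <- (base - sum(base) / n) / stats::sd(base)
  mean + sd * z
}

#' Expand a summary grid into moment-exact pseudo-replicates
#'
#' Applies [moment_replicates()] to every row of a summary table and returns
#' replicate-level observations suitable for [call_loaec()]. Experiments are
#' emulated by repeating the reconstruction once per `experiment` id, so the
#' within-group spread equals the tabulated SD in every experiment.
#'
#' @param cells A data frame with columns `material`, `endpoint`,
#'   `concentration_ug_per_ml`, `mean`, `sd` (e.g. `am_fixture()$summary`).
#' @param n Replicates per experiment (>= 2).
#' @param n_experiments Number of experiment ids to emit.
#' @return A tibble of observations with columns `material`, `endpoint`,
#'   `concentration_ug_per_ml`, `experiment`, `well`, `value`.
#' @export
#' @examples
#' fx <- am_fixture()
#' cells <- dplyr::filter(fx$summary, material == "Quartz DQ12", endpoint == "LDH")
#' pseudo_replicates(cells, n = 3)
pseudo_replicates <- function(cells, n = 3, n_experiments = 1) {
  check_columns(cells, c("material", "endpoint", "concentration_ug_per_ml", "mean", "sd"),
                "cells")
  if (n_experiments < 1) {
    abort("`n_experiments` must be >= 1.", class = "amtox_error_argument")
  }
  grid <- tidyr::expand_grid(
    cells[c("material", "endpoint", "concentration_ug_per_ml", "mean", "sd")],
    experiment = seq_len(n_experiments)
  )
  grid$value <- purrr::map2(grid$mean, grid$sd, moment_replicates, n = n)
  grid$well <- list(seq_len(n))
  out <- tidyr::unnest(grid, c("value", "well"))
  dplyr::select(out, "material", "endpoint", "concentration_ug_per_ml",
                "experiment", "well", "value")
}

observation_cols <- c("material", "endpoint", "concentration_ug_per_ml",
                      "experiment", "well", "value")

#' Read and write replicate-level observation files
#'
#' Observations are exchanged as UTF-8 CSV with columns `material`,
#' `endpoint`, `concentration_ug_per_ml`, `experiment`, `well`, `value`.
#' `write_observations()` followed by `read_observations()` round-trips
#' decimal-representable values exactly.
#'
#' @param path File path.
#' @param observations A data frame of observations.
#' @return `read_observations()` returns a tibble of observations;
#'   `write_observations()` returns `observations` invisibly.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "amtox_error_lookup")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  check_columns(raw, observation_cols, basename(path))
  known <- am_endpoints()$endpoint
  bad_ep <- which(!raw$endpoint %in% known)
  if (length(bad_ep) > 0) {
    abort(
      sprintf("Line %d: unknown endpoint '%s' (expected one of %s).",
              bad_ep[1] + 1L, raw$endpoint[bad_ep[1]], paste(known, collapse = ", ")),
      class = "amtox_error_parse"
    )
  }
  numify <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad) > 0 || anyNA(raw[[col]])) {
      line <- if (length(bad) > 0) bad[1] else which(is.na(raw[[col]]))[1]
      abort(sprintf("Line %d: non-numeric value in column '%s'.", line + 1L, col),
            class = "amtox_error_parse")
    }
    x
  }
  tibble::tibble(
    material = raw$material,
    endpoint = raw$endpoint,
    concentration_ug_per_ml = numify("concentration_ug_per_ml"),
    experiment = as.integer(numify("experiment")),
    well = as.integer(numify("well")),
    value = numify("value")
  )
}

#' @rdname read_observations
#' @export
write_observations <- function(observations, path) {
  check_columns(observations, observation_cols, "observations")
  readr::write_csv(observations[observation_cols], path)
  invisible(observations)
}
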