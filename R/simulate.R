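#' Dose-response parameters for the synthetic assay generator
#'
#' The generator draws replicate values around a monotone Hill curve,
#' `baseline + emax * c^hill / (ec50^hill + c^hill)`, with homoscedastic
#' Gaussian well noise (`sigma`) and an optional Gaussian experiment-level
#' offset (`experiment_offset_sd`). Defaults mirror a quiescent LDH readout:
#' baseline 20 % of the positive control and a well SD of 3 percentage
#' points, the magnitude typical of the vehicle-control rows of the packaged
#' summary grid. Values are not truncated at 0 or 100 %, so the ANOVA stage
#' sees unbiased noise.
#'
#' @param baseline Response at concentration 0, endpoint units.
#' @param emax Asymptotic effect size added at high concentration.
#' @param ec50 Half-effect concentration, ug/mL (> 0 when `emax != 0`).
#' @param hill Hill coefficient (>= 0).
#' @param sigma Well-level noise SD (>= 0).
#' @param experiment_offset_sd Between-experiment offset SD (>= 0; default 0,
#'   as the published summary data do not separate the two variance levels).
#' @return An object of class `am_dr_params`.
#' @export
dose_response_params <- function(baseline = 20, emax = 0, ec50 = 45, hill = 2,
                                 sigma = 3, experiment_offset_sd = 0) {
  if (emax != 0 && (!is.finite(ec50) || ec50 <= 0)) {
    abort("`ec50` must be > 0 when `emax` is non-zero.", class = "amtox_error_argument")
  }
  if (hill < 0 || sigma < 0 || experiment_offset_sd < 0) {
    abort("`hill`, `sigma` and `experiment_offset_sd` must be >= 0.",
          class = "amtox_error_argument")
  }
  structure(
    list(baseline = baseline, emax = emax, ec50 = ec50, hill = hill,
         sigma = sigma, experiment_offset_sd = experiment_offset_sd),
    class = "am_dr_params"
  )
}

#' Hill mean response at given concentrations
#'
#' @param params An [dose_response_params()] object.
#' @param concentration Concentrations, ug/mL.
#' @return Mean response values (the vehicle control, concentration 0,
#'   returns exactly `baseline`).
#' @export
hill_mean <- function(params, concentration) {
  stopifnot(inherits(params, "am_dr_params"))
  out <- rep(params$baseline, length(concentration))
  pos <- concentration > 0
  if (params$emax != 0 && any(pos)) {
    ch <- concentration[pos]^params$hill
    out[pos] <- params$baseline +
      params$emax * ch / (params$ec50^params$hill + ch)
  }
  out
}

#' Simulate replicate-level observations for one endpoint
#'
#' Generates `n_wells` wells x `n_experiments` independent experiments per
#' concentration, with values drawn as Hill mean + experiment offset + well
#' noise. The RNG state is set from `seed` locally (the caller's random
#' stream is untouched) so a fixed seed yields an identical dataset.
#'
#' @param params An [dose_response_params()] object.
#' @param series Concentration series including the vehicle control 0
#'   (default the standard series 0, 22.5, 45, 90, 180 ug/mL).
#' @param n_wells Wells (triplicate by default) per concentration and
#'   experiment.
#' @param n_experiments Number of independent experiments (default 3).
#' @param seed Integer seed; required for reproducibility.
#' @param material,endpoint Labels attached to the observations.
#' @return An observation tibble (see [read_observations()]).
#' @export
#' @examples
#' simulate_endpoint(dose_response_params(emax = 50), seed = 1)
simulate_endpoint <- function(params, series = c(0, 22.5, 45, 90, 180),
                              n_wells = 3, n_experiments = 3, seed,
                              material = "synthetic", endpoint = "LDH") {
  stopifnot(inherits(params, "am_dr_params"))
  if (missing(seed) || !is.numeric(seed)) {
    abort("An integer `seed` is required.", class = "amtox_error_argument")
  }
  if (series[1] != 0 || any(diff(series) <= 0)) {
    abort("`series` must start at 0 and increase strictly.",
          class = "amtox_error_argument")
  }
  if (n_wells < 1 || n_experiments < 1) {
    abort("`n_wells` and `n_experiments` must be >= 1.", class = "amtox_error_argument")
  }
  grid <- tidyr::expand_grid(
    concentration_ug_per_ml = series,
    experiment = seq_len(n_experiments),
    well = seq_len(n_wells)
  )
  mu <- hill_mean(params, grid$concentration_ug_per_ml)
  values <- withr::with_seed(as.integer(seed), {
    offsets <- rnorm(n_experiments, 0, params$experiment_offset_sd)
    mu + offsets[grid$experiment] + rnorm(nrow(grid), 0, params$sigma)
  })
  tibble::tibble(
    material = material,
    endpoint = endpoint,
    concentration_ug_per_ml = grid$concentration_ug_per_ml,
    experiment = grid$experiment,
    well = grid$well,
    value = values
  )
}

#' Simulate a full four-endpoint assay for one material
#'
#' @param endpoint_params Named list of [dose_response_params()], one per
#'   endpoint (`LDH`, `GLU`, `TNF`, `H2O2`); endpoints may be omitted.
#' @param series Concentration series shared by the endpoints (a named list
#'   of per-endpoint series is also accepted).
#' @inheritParams simulate_endpoint
#' @return An observation tibble covering the given endpoints.
#' @export
simulate_material <- function(endpoint_params, series = c(0, 22.5, 45, 90, 180),
                              n_wells = 3, n_experiments = 3, seed,
                              material = "synthetic") {
  if (is.null(names(endpoint_params)) ||
      !all(names(endpoint_params) %in% am_endpoints()$endpoint)) {
    abort("`endpoint_params` must be named with assay endpoints.",
          class = "amtox_error_argument")
  }
  eps <- names(endpoint_params)
  dplyr::bind_rows(purrr::imap(endpoint_params, function(p, ep) {
    s <- if (is.list(series)) series[[ep]] else series
    simulate_endpoint(p, series = s, n_wells = n_wells,
                      n_experiments = n_experiments,
                      seed = as.integer(seed) + match(ep, eps),
                      material = material, endpoint = ep)
  }))
}

#' Simulate replicates from the packaged summary grid
#'
#' Draws Normal(mean, sd) replicates per concentration from the packaged
#' mean/SD cells of one material x endpoint, e.g. to study how the LOAEC
#' stage behaves under the published effect sizes.
#'
#' @param material,endpoint Material and endpoint present in the fixture.
#' @param n_wells,n_experiments,seed As in [simulate_endpoint()].
#' @param fixture The fixture list from [am_fixture()].
#' @return An observation tibble.
#' @export
simulate_from_table2 <- function(material, endpoint, n_wells = 3,
                                 n_experiments = 3, seed,
                                 fixture = am_fixture()) {
  cells <- fixture$summary[fixture$summary$material == material &
                             fixture$summary$endpoint == endpoint, ]
  if (nrow(cells) == 0) {
    abort(sprintf("No summary cells for '%s' / '%s'.", material, endpoint),
          class = "amtox_error_data")
  }
  if (missing(seed) || !is.numeric(seed)) {
    abort("An integer `seed` is required.", class = "amtox_error_argument")
  }
  grid <- tidyr::expand_grid(
    cells[c("concentration_ug_per_ml", "mean", "sd")],
    experiment = seq_len(n_experiments),
    well = seq_len(n_wells)
  )
  values <- withr::with_seed(as.integer(seed), {
    rnorm(nrow(grid), grid$mean, grid$sd)
  })
  tibble::tibble(
    material = material,
    endpoint = endpoint,
    concentration_ug_per_ml = grid$concentration_ug_per_ml,
    experiment = grid$experiment,
    well = grid$well,
    value = values
  )
}

#' Monte-Carlo operating characteristics of the two-of-four rule
#'
#' Repeatedly simulates the four-endpoint assay under each scenario, runs the
#' LOAEC + threshold classification, and estimates the probability of an
#' `active` call with its binomial standard error. This quantifies the
#' robustness rationale of requiring at least two affected endpoints: a
#' strong effect confined to one endpoint should be called active at roughly
#' the chance level of the null scenario.
#'
#' @param scenarios A list of scenarios; each is a list with elements `name`,
#'   `bet_m2_per_g`, and `endpoint_params` (named list of
#'   [dose_response_params()] covering all four endpoints).
#' @param n_runs Simulation runs per scenario (>= 100).
#' @param seed Integer seed; per-run seeds are derived from it.
#' @param series,n_wells,n_experiments Assay design, as in
#'   [simulate_endpoint()].
#' @param config,geometry,threshold_mm2_per_ml Classification settings.
#' @return A tibble with one row per scenario: `scenario`, `n_runs`,
#'   `p_active`, `se`.
#' @export
operating_characteristics <- function(scenarios, n_runs = 200, seed,
                                      series = c(0, 22.5, 45, 90, 180),
                                      n_wells = 3, n_experiments = 3,
                                      config = stat_config(),
                                      geometry = culture_geometry(),
                                      threshold_mm2_per_ml = volume_threshold(geometry)) {
  if (n_runs < 100) {
    abort("`n_runs` must be >= 100 for a stable estimate.",
          class = "amtox_error_argument")
  }
  if (missing(seed) || !is.numeric(seed)) {
    abort("An integer `seed` is required.", class = "amtox_error_argument")
  }
  rows <- purrr::map2(scenarios, seq_along(scenarios), function(sc, i) {
    active <- vapply(seq_len(n_runs), function(run) {
      run_seed <- (as.integer(seed) + 7919L * i + run) %% .Machine$integer.max
      obs <- simulate_material(sc$endpoint_params, series = series,
                               n_wells = n_wells, n_experiments = n_experiments,
                               seed = run_seed, material = sc$name)
      loaec <- call_loaec_all(obs, config = config)
      mm2 <- ifelse(is.na(loaec$loaec_ug_per_ml), NA_real_,
                    loaec$loaec_ug_per_ml * sc$bet_m2_per_g)
      sum(!is.na(mm2) & mm2 < threshold_mm2_per_ml) >= 2
    }, logical(1))
    p <- mean(active)
    tibble::tibble(
      scenario = sc$name,
      n_runs = n_runs,
      p_active = p,
      se = sqrt(p * (1 - p) / n_runs)
    )
  })
  dplyr::bind_rows(rows)
}
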