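#' Flag endpoint LOAECs against the surface-area threshold
#'
#' Converts each mass-based in vitro LOAEC to its surface-area dose and flags
#' it: `below_threshold` if strictly below the threshold (a significant
#' effect below 6000 mm2/mL is interpreted as a particle-specific, biologically
#' relevant effect), `above_threshold` otherwise (attributed to cellular
#' overload), `not_significant` when no LOAEC was recorded, and
#' `not_determined` when the endpoint was not measured. Flags use the
#' unrounded surface dose; the rounded `mm2_reported` column is for display.
#'
#' @param loaec_table A data frame with columns `material`, `endpoint`,
#'   `loaec_ug_per_ml` (NA = not significant) and optionally `determined`.
#' @param materials Material registry with `name` and `bet_m2_per_g`
#'   (e.g. `am_fixture()$materials`).
#' @param threshold_mm2_per_ml Classification threshold, default
#'   `volume_threshold(geometry)`.
#' @param geometry A [culture_geometry()].
#' @return The input with added columns `bet_m2_per_g`, `mm2_per_ml`,
#'   `mm2_reported` and `flag`.
#' @export
flag_endpoints <- function(loaec_table, materials,
                           threshold_mm2_per_ml = volume_threshold(geometry),
                           geometry = culture_geometry()) {
  check_columns(loaec_table, c("material", "endpoint", "loaec_ug_per_ml"), "loaec_table")
  check_columns(materials, c("name", "bet_m2_per_g"), "materials")
  out <- dplyr::left_join(
    loaec_table,
    dplyr::select(materials, material = "name", "bet_m2_per_g"),
    by = "material"
  )
  unknown <- is.na(out$bet_m2_per_g) & !is.na(out$loaec_ug_per_ml)
  if (any(unknown)) {
    abort(
      sprintf("No BET surface area for material '%s'; cannot convert its LOAEC.",
              out$material[unknown][1]),
      class = "amtox_error_configuration"
    )
  }
  if (!"determined" %in% names(out)) out$determined <- TRUE
  out$mm2_per_ml <- ifelse(
    is.na(out$loaec_ug_per_ml), NA_real_,
    out$loaec_ug_per_ml * out$bet_m2_per_g
  )
  out$mm2_reported <- round_half_up(out$mm2_per_ml)
  out$flag <- dplyr::case_when(
    !out$determined ~ "not_determined",
    is.na(out$loaec_ug_per_ml) ~ "not_significant",
    out$mm2_per_ml < threshold_mm2_per_ml ~ "below_threshold",
    TRUE ~ "above_threshold"
  )
  out
}

#' Classify materials as active or passive with the two-of-four rule
#'
#' A material is assigned `active` only if significant in vitro LOAECs below
#' the surface-area threshold were recorded for at least `min_positive` of
#' the four endpoints; zero or one such endpoint gives `passive`. A single
#' undetermined endpoint is tolerated (the rule stays ">= 2 of the
#' determined endpoints"); with fewer than three determined endpoints the
#' material cannot be classified.
#'
#' @param flags A data frame as returned by [flag_endpoints()].
#' @param min_positive Minimum number of below-threshold endpoints for an
#'   active call (default 2).
#' @return A tibble with one row per material: `n_determined`, `n_below`,
#'   `call`, classed `am_classification`.
#' @export
classify_in_vitro <- function(flags, min_positive = 2) {
  check_columns(flags, c("material", "endpoint", "flag"), "flags")
  out <- dplyr::summarise(
    dplyr::group_by(flags, .data$material),
    n_determined = sum(.data$flag != "not_determined"),
    n_below = sum(.data$flag == "below_threshold"),
    .groups = "drop"
  )
  short <- out$n_determined < 3
  if (any(short)) {
    abort(
      sprintf("Material '%s' has only %d determined endpoint(s); >= 3 required.",
              out$material[short][1], out$n_determined[short][1]),
      class = "amtox_error_insufficient"
    )
  }
  out$call <- ifelse(out$n_below >= min_positive, "active", "passive")
  class(out) <- c("am_classification", class(out))
  out
}

#' Categorize in vivo STIS records as active or passive
#'
#' The in vivo reference categorization: a material is `active` if its 5-day
#' equivalent NOAEC is below 10 mg/m3, `passive` if no treatment-related
#' findings occurred at 10 mg/m3 or higher. 28-day NOAECs are first scaled
#' with [five_day_noaec()]; bound qualifiers propagate (an upper-bound NOAEC
#' "<x" with x <= 10 is active, a lower-bound ">=x" with x >= 10 passive).
#'
#' @param stis STIS records with columns `material`, `noaec_mg_m3`,
#'   `noaec_bound`, `exposure_days` (e.g. `am_fixture()$stis`).
#' @param cutoff_mg_m3 Category cutoff (default 10 mg/m3).
#' @return The input with added columns `noaec_5day_mg_m3` and
#'   `in_vivo_category`.
#' @export
categorize_in_vivo <- function(stis, cutoff_mg_m3 = 10) {
  check_columns(stis, c("material", "noaec_mg_m3", "noaec_bound", "exposure_days"),
                "stis")
  if (anyNA(stis$noaec_mg_m3)) {
    abort(
      sprintf("Missing NOAEC for material '%s'.",
              stis$material[is.na(stis$noaec_mg_m3)][1]),
      class = "amtox_error_data"
    )
  }
  scaled <- five_day_noaec(stis$noaec_mg_m3, stis$exposure_days)
  category <- dplyr::case_when(
    stis$noaec_bound == "below" & scaled <= cutoff_mg_m3 ~ "active",
    stis$noaec_bound == "below" ~ NA_character_,
    scaled < cutoff_mg_m3 ~ "active",
    TRUE ~ "passive"
  )
  if (anyNA(category)) {
    abort(
      sprintf("Indeterminate in vivo category for '%s': upper-bound NOAEC above the cutoff.",
              stis$material[is.na(category)][1]),
      class = "amtox_error_data"
    )
  }
  dplyr::mutate(stis, noaec_5day_mg_m3 = scaled, in_vivo_category = category)
}

#' Cooper statistics for a set of in vitro / in vivo call pairs
#'
#' Cross-tabulates the in vitro calls against the in vivo reference
#' categories (the truth axis) and derives sensitivity, specificity,
#' accuracy, and positive/negative predictive values. Percentages are kept
#' unrounded; `reported` columns round to integer percent as concordance
#' tables are conventionally printed. Undefined ratios (empty margins) are
#' returned as `NA`.
#'
#' @param pairs A data frame with columns `in_vitro` and `in_vivo`, each
#'   `"active"` or `"passive"`.
#' @return An object of class `am_cooper`; see [tidy.am_cooper()].
#' @export
#' @examples
#' cooper_statistics(data.frame(
#'   in_vitro = c("active", "active", "passive"),
#'   in_vivo = c("active", "passive", "passive")
#' ))
cooper_statistics <- function(pairs) {
  check_columns(pairs, c("in_vitro", "in_vivo"), "pairs")
  if (nrow(pairs) == 0) {
    abort("At least one call pair is required.", class = "amtox_error_argument")
  }
  ok <- c("active", "passive")
  if (!all(pairs$in_vitro %in% ok) || !all(pairs$in_vivo %in% ok)) {
    abort("Calls must be 'active' or 'passive'.", class = "amtox_error_argument")
  }
  tp <- sum(pairs$in_vitro == "active" & pairs$in_vivo == "active")
  fp <- sum(pairs$in_vitro == "active" & pairs$in_vivo == "passive")
  fn <- sum(pairs$in_vitro == "passive" & pairs$in_vivo == "active")
  tn <- sum(pairs$in_vitro == "passive" & pairs$in_vivo == "passive")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(
      tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp),
      accuracy = ratio(tp + tn, tp + fp + fn + tn),
      ppv = ratio(tp, tp + fp),
      npv = ratio(tn, tn + fn)
    ),
    class = "am_cooper"
  )
}

#' @export
print.am_cooper <- function(x, ...) {
  cat("Cooper statistics (in vivo reference)\n")
  cat(sprintf("              vivo active  vivo passive\n"))
  cat(sprintf("vitro active  %11d  %12d\n", x$tp, x$fp))
  cat(sprintf("vitro passive %11d  %12d\n", x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.0f %%", round_half_up(v))
  cat(sprintf("sensitivity %s, specificity %s, accuracy %s, PPV %s, NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy),
              fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Tidiers for Cooper statistics
#'
#' `tidy()` returns one row per derived metric with the unrounded and the
#' integer-rounded (as conventionally printed) percentage; `glance()` returns
#' the confusion counts and metrics in one row.
#'
#' @param x An `am_cooper` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.am_cooper <- function(x, ...) {
  metrics <- c(sensitivity = x$sensitivity, specificity = x$specificity,
               accuracy = x$accuracy, ppv = x$ppv, npv = x$npv)
  tibble::tibble(
    metric = names(metrics),
    percent = as.numeric(metrics),
    reported = round_half_up(as.numeric(metrics))
  )
}

#' @rdname tidy.am_cooper
#' @export
glance.am_cooper <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy, ppv = x$ppv, npv = x$npv
  )
}

#' Run the prediction model from a LOAEC table
#'
#' Orchestrates the classification stages: surface-area conversion and
#' threshold flagging, the two-of-four active/passive rule, in vivo
#' categorization of the STIS records, and Cooper concordance statistics.
#' Only materials with an STIS record of role `"test"` (or all STIS materials
#' when no `role` column is present) enter the concordance table; benchmark
#' controls are classified but not counted.
#'
#' @param loaec_table Mass-based LOAEC table (columns `material`, `endpoint`,
#'   `loaec_ug_per_ml`, optionally `determined`), e.g. `am_fixture()$loaec`
#'   or the output of [call_loaec_all()].
#' @param materials Material registry with BET areas.
#' @param stis STIS records (see [categorize_in_vivo()]).
#' @param geometry A [culture_geometry()].
#' @param threshold_mm2_per_ml Classification threshold, default from
#'   `geometry` (6000 mm2/mL).
#' @param min_positive Endpoints below threshold required for activity.
#' @return A list of class `am_prediction` with elements `flags`,
#'   `classification`, `in_vivo`, `comparison` (per-material calls side by
#'   side) and `cooper`.
#' @export
#' @examples
#' fx <- am_fixture()
#' pred <- run_prediction_model(fx$loaec, fx$materials, fx$stis)
#' pred$cooper
run_prediction_model <- function(loaec_table, materials, stis,
                                 geometry = culture_geometry(),
                                 threshold_mm2_per_ml = volume_threshold(geometry),
                                 min_positive = 2) {
  if (nrow(loaec_table) == 0) {
    empty <- tibble::tibble(material = character(), in_vitro = character(),
                            in_vivo = character())
    return(structure(list(flags = loaec_table, classification = empty,
                          in_vivo = stis, comparison = empty, cooper = NULL),
                     class = "am_prediction"))
  }
  flags <- flag_endpoints(loaec_table, materials,
                          threshold_mm2_per_ml = threshold_mm2_per_ml,
                          geometry = geometry)
  classification <- classify_in_vitro(flags, min_positive = min_positive)
  in_vivo <- categorize_in_vivo(stis)
  test_set <- if ("role" %in% names(in_vivo)) {
    in_vivo[in_vivo$role == "test", ]
  } else {
    in_vivo
  }
  comparison <- dplyr::inner_join(
    dplyr::select(classification, "material", in_vitro = "call"),
    dplyr::select(test_set, "material", in_vivo = "in_vivo_category"),
    by = "material"
  )
  cooper <- if (nrow(comparison) > 0) {
    cooper_statistics(comparison)
  } else {
    NULL
  }
  structure(
    list(flags = flags, classification = classification, in_vivo = in_vivo,
         comparison = comparison, cooper = cooper),
    class = "am_prediction"
  )
}

#' @export
print.am_prediction <- function(x, ...) {
  cat(sprintf("AM assay prediction model: %d material(s) classified\n",
              nrow(x$classification)))
  print(tibble::as_tibble(x$classification))
  if (!is.null(x$cooper)) print(x$cooper)
  invisible(x)
}

#' Run the full pipeline from replicate-level observations
#'
#' Calls the in vitro LOAEC for every material x endpoint with
#' [call_loaec_all()] and feeds the result through [run_prediction_model()].
#' Endpoints absent from the observations for a material are carried as
#' not determined.
#'
#' @param observations Replicate-level observations (see
#'   [read_observations()]).
#' @param materials,stis,geometry,threshold_mm2_per_ml,min_positive Passed to
#'   [run_prediction_model()].
#' @param config A [stat_config()] for the LOAEC stage.
#' @return An `am_prediction` list; see [run_prediction_model()].
#' @export
run_pipeline <- function(observations, materials, stis,
                         config = stat_config(),
                         geometry = culture_geometry(),
                         threshold_mm2_per_ml = volume_threshold(geometry),
                         min_positive = 2) {
  loaec_table <- call_loaec_all(observations, config = config)
  if (nrow(loaec_table) > 0) {
    grid <- tidyr::expand_grid(material = unique(loaec_table$material),
                               endpoint = am_endpoints()$endpoint)
    loaec_table <- dplyr::left_join(grid, loaec_table,
                                    by = c("material", "endpoint"))
    loaec_table$determined <- !is.na(loaec_table$comparator)
    loaec_table$comparator <- NULL
  }
  run_prediction_model(loaec_table, materials, stis, geometry = geometry,
                       threshold_mm2_per_ml = threshold_mm2_per_ml,
                       min_positive = min_positive)
}
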