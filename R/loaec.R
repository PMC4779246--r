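#' Configuration for the LOAEC statistics stage
#'
#' @param alpha Significance level; effects with adjusted p <= `alpha` are
#'   called significant (ties at `alpha` count, default 0.05).
#' @param sidedness `"two_sided"` (default; the assay also records decreases,
#'   e.g. TNF-alpha inhibition at cytotoxic ZnO doses) or `"greater"`.
#' @param comparator `"vehicle_control"` (default) or `"corundum_benchmark"`.
#' @param anova `"two_way"` (concentration + experiment, default) or
#'   `"one_way"` (concentration only).
#' @return An object of class `am_stat_config`.
#' @export
stat_config <- function(alpha = 0.05,
                        sidedness = c("two_sided", "greater"),
                        comparator = c("vehicle_control", "corundum_benchmark"),
                        anova = c("two_way", "one_way")) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "amtox_error_argument")
  }
  structure(
    list(
      alpha = alpha,
      sidedness = match.arg(sidedness),
      comparator = match.arg(comparator),
      anova = match.arg(anova)
    ),
    class = "am_stat_config"
  )
}

#' Two-way ANOVA for one material and endpoint
#'
#' Fits the fixed-effects model `value ~ concentration + experiment` (no
#' interaction) on a crossed concentration-by-experiment layout and returns
#' the effect table together with the pooled residual variance and degrees of
#' freedom consumed by the Dunnett step. With a single experiment the model
#' degrades to a one-way ANOVA on concentration.
#'
#' @param data A data frame with columns `concentration_ug_per_ml`,
#'   `experiment`, `value`.
#' @return A list with `effects` (tibble: term, df, sumsq, meansq, statistic,
#'   p_value), `residual_df` and `residual_variance`.
#' @export
anova_two_way <- function(data) {
  check_columns(data, c("concentration_ug_per_ml", "experiment", "value"), "data")
  conc <- factor(data$concentration_ug_per_ml)
  expt <- factor(data$experiment)
  if (nlevels(expt) > 1) {
    cells <- table(conc, expt)
    if (any(cells == 0)) {
      idx <- which(cells == 0, arr.ind = TRUE)[1, ]
      abort(
        sprintf("Empty cell in the concentration x experiment layout: concentration %s, experiment %s.",
                rownames(cells)[idx[1]], colnames(cells)[idx[2]]),
        class = "amtox_error_layout"
      )
    }
    fit <- lm(data$value ~ conc + expt)
  } else {
    fit <- lm(data$value ~ conc)
  }
  # degenerate (perfect-fit) layouts are handled downstream; silence the
  # corresponding anova.lm warning
  tab <- suppressWarnings(anova(fit))
  effects <- tibble::tibble(
    term = rownames(tab),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
  res <- effects[effects$term == "Residuals", ]
  list(
    effects = effects,
    residual_df = res$df,
    residual_variance = res$meansq
  )
}

# Dunnett many-to-one adjusted p-values from group summaries.
# tstat: per-group t statistics against the shared control; n: group sizes;
# n0: control size; df: residual df. The contrasts share the control, so the
# comparisons are equicorrelated with corr_ij = lambda_i * lambda_j,
# lambda_i = sqrt(n_i / (n_i + n0)) (1/2 in the balanced case). The
# multivariate-t integral is evaluated under a locally fixed RNG state so
# repeated calls are reproducible to the integration tolerance without
# disturbing the caller's random stream.
dunnett_p_from_t <- function(tstat, n, n0, df, sidedness = "two_sided") {
  k <- length(tstat)
  lambda <- sqrt(n / (n + n0))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  alg <- mvtnorm::GenzBretz(abseps = 5e-4, maxpts = 25000)
  vapply(tstat, function(t_i) {
    if (!is.finite(t_i)) return(NA_real_)
    p <- withr::with_seed(20160305, {
      if (sidedness == "two_sided") {
        1 - mvtnorm::pmvt(lower = rep(-abs(t_i), k), upper = rep(abs(t_i), k),
                          df = df, corr = corr, algorithm = alg)
      } else {
        1 - mvtnorm::pmvt(lower = rep(-Inf, k), upper = rep(t_i, k),
                          df = df, corr = corr, algorithm = alg)
      }
    })
    min(max(as.numeric(p), 0), 1)
  }, numeric(1))
}

#' Dunnett many-to-one adjusted p-values against the vehicle control
#'
#' Compares every treated concentration group with the shared vehicle control
#' using Dunnett's multiple-comparison procedure: t statistics built on the
#' pooled residual variance of the two-way ANOVA, referred to the
#' multivariate t distribution with the ANOVA residual degrees of freedom and
#' the correlation induced by the shared control (1/2 in the balanced case).
#'
#' @param data A data frame with columns `concentration_ug_per_ml`,
#'   `experiment`, `value`, containing the vehicle control (concentration 0)
#'   and at least one treated group, each with >= 2 replicates.
#' @param config A [stat_config()].
#' @return A tibble with one row per treated concentration: `concentration_ug_per_ml`,
#'   `n`, `estimate` (mean difference to control), `statistic`, `df`, `p_adj`.
#' @export
dunnett_adjusted_p <- function(data, config = stat_config()) {
  check_columns(data, c("concentration_ug_per_ml", "experiment", "value"), "data")
  stopifnot(inherits(config, "am_stat_config"))
  if (!any(data$concentration_ug_per_ml == 0)) {
    abort("Vehicle control (concentration 0) is missing.", class = "amtox_error_argument")
  }
  sizes <- table(data$concentration_ug_per_ml)
  if (any(sizes < 2)) {
    abort(
      sprintf("Every group needs >= 2 replicates (concentration %s has %d).",
              names(sizes)[sizes < 2][1], min(sizes)),
      class = "amtox_error_argument"
    )
  }
  fit <- if (config$anova == "two_way") {
    anova_two_way(data)
  } else {
    anova_two_way(dplyr::mutate(data, experiment = 1L))
  }
  degenerate_tol <- .Machine$double.eps^0.75 * max(1, stats::var(data$value))
  if (!is.finite(fit$residual_variance) || fit$residual_variance <= degenerate_tol) {
    abort("Zero residual variance: data are degenerate for the Dunnett step.",
          class = "amtox_error_degenerate")
  }
  means <- tapply(data$value, data$concentration_ug_per_ml, mean)
  concs <- as.numeric(names(means))
  ord <- order(concs)
  means <- means[ord]; concs <- concs[ord]
  ns <- as.numeric(sizes[as.character(concs)])
  treated <- concs != 0
  n0 <- ns[!treated]
  est <- means[treated] - means[!treated]
  se <- sqrt(fit$residual_variance * (1 / ns[treated] + 1 / n0))
  tstat <- est / se
  p_adj <- dunnett_p_from_t(tstat, ns[treated], n0, fit$residual_df,
                            config$sidedness)
  tibble::tibble(
    concentration_ug_per_ml = concs[treated],
    n = as.integer(ns[treated]),
    estimate = unname(as.numeric(est)),
    statistic = unname(as.numeric(tstat)),
    df = fit$residual_df,
    p_adj = unname(p_adj)
  )
}

new_loaec <- function(material, endpoint, p_table, config, comparator) {
  sig <- p_table$p_adj <= config$alpha
  loaec <- if (any(sig, na.rm = TRUE)) {
    min(p_table$concentration_ug_per_ml[which(sig)])
  } else {
    NA_real_
  }
  structure(
    list(
      material = material,
      endpoint = endpoint,
      loaec_ug_per_ml = loaec,
      significant = !is.na(loaec),
      p_table = p_table,
      alpha = config$alpha,
      sidedness = config$sidedness,
      comparator = comparator
    ),
    class = "am_loaec"
  )
}

#' Call the in vitro LOAEC for one material and endpoint
#'
#' The in vitro LOAEC is the lowest concentration at which a significant
#' effect (Dunnett-adjusted p <= alpha against the vehicle control) is
#' recorded, regardless of whether intermediate higher concentrations are
#' non-significant. If no concentration is significant the result carries
#' `loaec_ug_per_ml = NA` ("n.s.").
#'
#' @param data Observations with columns `concentration_ug_per_ml`,
#'   `experiment`, `value`, optionally `material` and `endpoint` (used to
#'   subset when `material`/`endpoint` are given).
#' @param material,endpoint Optional labels; when the data contain several
#'   materials or endpoints they select which one to analyse.
#' @param config A [stat_config()].
#' @return An object of class `am_loaec`; see [tidy.am_loaec()].
#' @export
#' @examples
#' fx <- am_fixture()
#' cells <- dplyr::filter(fx$summary, material == "Quartz DQ12", endpoint == "LDH")
#' obs <- pseudo_replicates(cells, n = 3)
#' call_loaec(obs)
call_loaec <- function(data, material = NULL, endpoint = NULL,
                       config = stat_config()) {
  if (!is.null(material) && "material" %in% names(data)) {
    data <- data[data$material == material, , drop = FALSE]
  }
  if (!is.null(endpoint) && "endpoint" %in% names(data)) {
    data <- data[data$endpoint == endpoint, , drop = FALSE]
  }
  material <- material %||%
    (if ("material" %in% names(data)) unique(data$material)[1] else NA_character_)
  endpoint <- endpoint %||%
    (if ("endpoint" %in% names(data)) unique(data$endpoint)[1] else NA_character_)
  if (nrow(data) == 0) {
    abort("No observations to analyse.", class = "amtox_error_argument")
  }
  if (!any(data$concentration_ug_per_ml == 0)) {
    abort("Vehicle control (concentration 0) is missing.", class = "amtox_error_argument")
  }
  p_table <- dunnett_adjusted_p(data, config)
  new_loaec(material, endpoint, p_table, config, comparator = "vehicle_control")
}

#' Call the in vitro LOAEC against the corundum benchmark
#'
#' Alternative evaluation mode: each treated concentration is compared with
#' the negative benchmark material (corundum) measured at the equal particle
#' concentration, by pooled-variance two-sample t tests with Holm adjustment
#' across concentrations.
#'
#' @param data Observations for the test material (columns
#'   `concentration_ug_per_ml`, `experiment`, `value`).
#' @param benchmark_data Observations for the benchmark material at the same
#'   concentrations.
#' @inheritParams call_loaec
#' @return An object of class `am_loaec` with comparator
#'   `"corundum_benchmark"`.
#' @export
call_loaec_vs_benchmark <- function(data, benchmark_data, material = NULL,
                                    endpoint = NULL, config = stat_config()) {
  check_columns(data, c("concentration_ug_per_ml", "value"), "data")
  check_columns(benchmark_data, c("concentration_ug_per_ml", "value"), "benchmark_data")
  material <- material %||%
    (if ("material" %in% names(data)) unique(data$material)[1] else NA_character_)
  endpoint <- endpoint %||%
    (if ("endpoint" %in% names(data)) unique(data$endpoint)[1] else NA_character_)
  concs <- sort(unique(data$concentration_ug_per_ml))
  concs <- concs[concs > 0]
  bench_concs <- unique(benchmark_data$concentration_ug_per_ml)
  if (!all(concs %in% bench_concs)) {
    abort(
      sprintf("Benchmark lacks concentration(s): %s.",
              paste(setdiff(concs, bench_concs), collapse = ", ")),
      class = "amtox_error_argument"
    )
  }
  alternative <- if (config$sidedness == "two_sided") "two.sided" else "greater"
  rows <- purrr::map(concs, function(cc) {
    x <- data$value[data$concentration_ug_per_ml == cc]
    y <- benchmark_data$value[benchmark_data$concentration_ug_per_ml == cc]
    if (length(x) < 2 || length(y) < 2) {
      abort(sprintf("Concentration %s needs >= 2 replicates on both sides.", cc),
            class = "amtox_error_argument")
    }
    if (stats::var(x) + stats::var(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
      tt <- list(estimate = c(mean(x), mean(y)), statistic = NA_real_,
                 parameter = NA_real_, p.value = p)
    } else {
      tt <- t.test(x, y, var.equal = TRUE, alternative = alternative)
    }
    tibble::tibble(
      concentration_ug_per_ml = cc,
      n = length(x),
      estimate = mean(x) - mean(y),
      statistic = as.numeric(tt$statistic),
      df = as.numeric(tt$parameter),
      p_raw = tt$p.value
    )
  })
  p_table <- dplyr::bind_rows(rows)
  p_table$p_adj <- p.adjust(p_table$p_raw, method = "holm")
  new_loaec(material, endpoint, p_table[, c("concentration_ug_per_ml", "n",
                                            "estimate", "statistic", "df", "p_adj")],
            config, comparator = "corundum_benchmark")
}

#' Call LOAECs for every material x endpoint in an observation table
#'
#' Maps [call_loaec()] over all material/endpoint combinations and binds the
#' tidied one-row results, giving the mass-based LOAEC table that feeds the
#' classification stage.
#'
#' @param observations Observation tibble (see [read_observations()]).
#' @param config A [stat_config()].
#' @return A tibble with columns `material`, `endpoint`, `loaec_ug_per_ml`,
#'   `significant`, `comparator`.
#' @export
call_loaec_all <- function(observations, config = stat_config()) {
  check_columns(observations, observation_cols, "observations")
  if (nrow(observations) == 0) {
    return(tibble::tibble(material = character(), endpoint = character(),
                          loaec_ug_per_ml = numeric(), significant = logical(),
                          comparator = character()))
  }
  groups <- dplyr::group_split(dplyr::group_by(observations, .data$material, .data$endpoint))
  dplyr::bind_rows(purrr::map(groups, function(g) {
    tidy(call_loaec(g, config = config))
  }))
}

#' @export
print.am_loaec <- function(x, ...) {
  loaec <- if (x$significant) sprintf("%g ug/mL", x$loaec_ug_per_ml) else "n.s."
  cat(sprintf("In vitro LOAEC [%s, %s]: %s (alpha = %g, %s, vs %s)\n",
              x$material, x$endpoint, loaec, x$alpha, x$sidedness, x$comparator))
  print(x$p_table)
  invisible(x)
}

#' Tidiers for LOAEC results
#'
#' `tidy()` returns the one-row LOAEC call; `glance()` returns the adjusted
#' p-value per concentration in wide form together with the test settings.
#'
#' @param x An `am_loaec` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.am_loaec <- function(x, ...) {
  tibble::tibble(
    material = x$material,
    endpoint = x$endpoint,
    loaec_ug_per_ml = x$loaec_ug_per_ml,
    significant = x$significant,
    comparator = x$comparator
  )
}

#' @rdname tidy.am_loaec
#' @export
glance.am_loaec <- function(x, ...) {
  tibble::tibble(
    material = x$material,
    endpoint = x$endpoint,
    alpha = x$alpha,
    sidedness = x$sidedness,
    comparator = x$comparator,
    n_concentrations = nrow(x$p_table),
    min_p_adj = min(x$p_table$p_adj, na.rm = TRUE)
  )
}
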