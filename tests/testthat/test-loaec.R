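make_balanced <- function(effects = c(0, 0, 5, 10), sigma = 2, n_wells = 3,
                          n_experiments = 3, exp_shift = c(0, 1, -1), seed = 1) {
  concs <- c(0, 22.5, 45, 90, 180)
  grid <- expand.grid(concentration_ug_per_ml = concs,
                      experiment = seq_len(n_experiments),
                      well = seq_len(n_wells))
  mu <- c(0, effects)[match(grid$concentration_ug_per_ml, concs)] +
    exp_shift[grid$experiment]
  withr::with_seed(seed, {
    grid$value <- 20 + mu + rnorm(nrow(grid), 0, sigma)
  })
  grid
}

test_that("two-way ANOVA matches a direct projection computation", {
  d <- make_balanced()
  fit <- anova_two_way(d)

  # brute-force sums of squares for the balanced additive layout
  grand <- mean(d$value)
  conc_means <- tapply(d$value, d$concentration_ug_per_ml, mean)
  exp_means <- tapply(d$value, d$experiment, mean)
  n_conc <- table(d$concentration_ug_per_ml)
  n_exp <- table(d$experiment)
  ss_conc <- sum(n_conc * (conc_means - grand)^2)
  ss_exp <- sum(n_exp * (exp_means - grand)^2)
  ss_tot <- sum((d$value - grand)^2)
  ss_res <- ss_tot - ss_conc - ss_exp

  eff <- fit$effects
  expect_equal(eff$sumsq[eff$term == "conc"], ss_conc)
  expect_equal(eff$sumsq[eff$term == "expt"], ss_exp)
  expect_equal(eff$sumsq[eff$term == "Residuals"], ss_res)
  expect_equal(fit$residual_df, 45 - 5 - 2)
  expect_equal(fit$residual_variance, ss_res / 38)

  # all-equal data: every effect sum of squares is zero
  d0 <- d; d0$value <- 7
  fit0 <- anova_two_way(d0)
  expect_equal(fit0$effects$sumsq, rep(0, 3))

  # single experiment degrades to one-way with residual df N - k
  d1 <- d[d$experiment == 1, ]
  fit1 <- anova_two_way(d1)
  expect_equal(fit1$residual_df, nrow(d1) - 5)
  expect_false("expt" %in% fit1$effects$term)

  # a hole in the crossed layout is a layout error naming the cell
  dd <- d[!(d$concentration_ug_per_ml == 45 & d$experiment == 2), ]
  expect_error(anova_two_way(dd), "45", class = "amtox_error_layout")
})

test_that("Dunnett adjusted p-values behave as a many-to-one procedure", {
  # no effect anywhere: nothing significant
  d <- make_balanced(effects = c(0, 0, 0, 0), seed = 2)
  tab <- dunnett_adjusted_p(d)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$p_adj > 0.05))

  # a 10-pooled-SD shift is detected with a vanishing p-value
  d10 <- make_balanced(effects = c(0, 0, 0, 20), sigma = 2, seed = 3)
  tab10 <- dunnett_adjusted_p(d10)
  expect_lt(tab10$p_adj[tab10$concentration_ug_per_ml == 180], 1e-4)

  # multiplicity: adjusted p never undercuts the unadjusted p of the same
  # contrast (same pooled-error t statistic and residual df)
  for (seed in 1:5) {
    d <- make_balanced(effects = c(2, 4, 6, 8), sigma = 4, seed = seed)
    tab <- dunnett_adjusted_p(d)
    p_raw <- 2 * pt(-abs(tab$statistic), tab$df)
    expect_true(all(tab$p_adj + 1e-6 >= p_raw))
  }

  # repeated evaluation on the same data is bitwise reproducible
  d <- make_balanced(seed = 4)
  expect_identical(dunnett_adjusted_p(d)$p_adj, dunnett_adjusted_p(d)$p_adj)

  expect_error(dunnett_adjusted_p(d[d$concentration_ug_per_ml > 0, ]),
               class = "amtox_error_argument")
  d2 <- d[!(d$concentration_ug_per_ml == 90 & !(d$experiment == 1 & d$well == 1)), ]
  expect_error(dunnett_adjusted_p(d2), class = "amtox_error_argument")
  d3 <- d; d3$value <- 1
  expect_error(dunnett_adjusted_p(d3), class = "amtox_error_degenerate")
})

test_that("Dunnett tail probabilities agree with a Monte-Carlo oracle", {
  # fix a balanced layout and compare the adjusted p at a moderate statistic
  # with the empirical max-|T| tail from the sampling distribution
  d <- make_balanced(effects = c(0, 0, 0, 0), sigma = 2, seed = 8)
  tab <- dunnett_adjusted_p(d)
  i <- which.max(abs(tab$statistic))
  t_obs <- tab$statistic[i]
  p_mc <- mc_dunnett_tail(t_obs, k = 4, n = 9, n0 = 9, df = 38,
                          n_draws = 2e5, seed = 42)
  se <- sqrt(p_mc * (1 - p_mc) / 2e5)
  expect_lt(abs(tab$p_adj[i] - p_mc), 4 * se + 1e-3)
})

test_that("Dunnett adjusted p-values cross-check against multcomp::glht", {
  skip_if_not_installed("multcomp")
  d <- make_balanced(effects = c(1, 3, 6, 9), sigma = 3, seed = 10)
  tab <- dunnett_adjusted_p(d)
  fit <- stats::aov(value ~ factor(concentration_ug_per_ml) + factor(experiment),
                    data = d)
  gl <- summary(multcomp::glht(
    fit, linfct = multcomp::mcp("factor(concentration_ug_per_ml)" = "Dunnett")
  ))
  expect_equal(tab$p_adj, as.numeric(gl$test$pvalues), tolerance = 5e-3)
})

test_that("call_loaec recovers a designed LOAEC and is order-invariant", {
  obs <- simulate_endpoint(high_dose_params(shift_sd = 10), seed = 21)
  res <- call_loaec(obs)
  expect_s3_class(res, "am_loaec")
  expect_true(res$significant)
  expect_equal(res$loaec_ug_per_ml, 90)
  expect_equal(tidy(res)$loaec_ug_per_ml, 90)
  expect_equal(tidy(res)$comparator, "vehicle_control")

  # shuffling rows and relabeling experiment ids changes nothing
  withr::with_seed(1, {
    shuffled <- obs[sample(nrow(obs)), ]
  })
  shuffled$experiment <- c(7L, 2L, 9L)[shuffled$experiment]
  res2 <- call_loaec(shuffled)
  expect_equal(res2$loaec_ug_per_ml, res$loaec_ug_per_ml)
  expect_equal(sort(res2$p_table$p_adj), sort(res$p_table$p_adj),
               tolerance = 1e-12)

  expect_error(call_loaec(obs[obs$concentration_ug_per_ml > 0, ]),
               class = "amtox_error_argument")
})

test_that("positive shifts from a centered null never raise an adjusted p", {
  # all groups share mean 20 and SD 3 exactly (estimates start at 0)
  cells <- data.frame(material = "x", endpoint = "LDH",
                      concentration_ug_per_ml = c(0, 22.5, 45, 90, 180),
                      mean = 20, sd = 3)
  base <- pseudo_replicates(cells, n = 3, n_experiments = 2)
  p0 <- dunnett_adjusted_p(base)$p_adj
  expect_true(all(p0 > 0.99))
  for (shift in c(2, 5, 10)) {
    d <- base
    treat <- d$concentration_ug_per_ml > 0
    d$value[treat] <- d$value[treat] + shift
    p1 <- dunnett_adjusted_p(d)$p_adj
    expect_true(all(p1 <= p0 + 1e-6))
    p0 <- p1
  }
})

test_that("corundum-benchmark mode compares per concentration with Holm", {
  bench <- simulate_endpoint(null_params(), seed = 40, material = "Corundum")
  same <- simulate_endpoint(null_params(), seed = 41)
  res <- call_loaec_vs_benchmark(same, bench)
  expect_false(res$significant)
  expect_equal(res$comparator, "corundum_benchmark")
  expect_equal(tidy(res)$comparator, "corundum_benchmark")

  shifted <- same
  shifted$value[shifted$concentration_ug_per_ml > 0] <-
    shifted$value[shifted$concentration_ug_per_ml > 0] + 30 # 10 sigma
  res2 <- call_loaec_vs_benchmark(shifted, bench)
  expect_true(res2$significant)
  expect_equal(res2$loaec_ug_per_ml, 22.5)

  # material identical to the benchmark data is never significant
  res3 <- call_loaec_vs_benchmark(bench, bench)
  expect_false(res3$significant)

  short <- bench[bench$concentration_ug_per_ml != 90, ]
  expect_error(call_loaec_vs_benchmark(same, short),
               class = "amtox_error_argument")
})

test_that("call_loaec_all maps over material x endpoint", {
  obs <- dplyr::bind_rows(
    simulate_endpoint(high_dose_params(), seed = 50, material = "A", endpoint = "LDH"),
    simulate_endpoint(null_params(), seed = 51, material = "A", endpoint = "GLU"),
    simulate_endpoint(potent_params(), seed = 52, material = "B", endpoint = "LDH")
  )
  out <- call_loaec_all(obs)
  expect_equal(nrow(out), 3)
  expect_equal(out$loaec_ug_per_ml[out$material == "A" & out$endpoint == "LDH"], 90)
  expect_true(is.na(out$loaec_ug_per_ml[out$material == "A" & out$endpoint == "GLU"]))
  expect_equal(out$loaec_ug_per_ml[out$material == "B"], 22.5)

  empty <- call_loaec_all(obs[0, ])
  expect_equal(nrow(empty), 0)
})
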