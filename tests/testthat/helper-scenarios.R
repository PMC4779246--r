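# Shared simulation scenarios for the statistics and classification tests.

# Quiescent endpoint: no dose effect, well SD 3 (vehicle-control magnitude).
null_params <- function(sigma = 3) {
  dose_response_params(baseline = 20, emax = 0, sigma = sigma)
}

# Potent endpoint: effect of `shift_sd` pooled SDs from the lowest tested
# concentration upwards (ec50 far below the series).
potent_params <- function(shift_sd = 8, sigma = 3) {
  dose_response_params(baseline = 20, emax = shift_sd * sigma, ec50 = 2,
                       hill = 4, sigma = sigma)
}

# Steep endpoint: ~10 SD effect at 90 and 180 ug/mL, negligible below
# (fraction of emax at 45 ug/mL is ~1 %).
high_dose_params <- function(shift_sd = 10, sigma = 3) {
  dose_response_params(baseline = 20, emax = shift_sd * sigma, ec50 = 65,
                       hill = 12, sigma = sigma)
}

four_endpoint_scenario <- function(name, bet, ldh = null_params(),
                                   glu = null_params(), tnf = null_params(),
                                   h2o2 = null_params()) {
  list(name = name, bet_m2_per_g = bet,
       endpoint_params = list(LDH = ldh, GLU = glu, TNF = tnf, H2O2 = h2o2))
}

# Empirical max-|T| tail probability for the balanced many-to-one layout:
# an independent Monte-Carlo oracle for the Dunnett adjustment, built from
# the sampling distribution directly (group means ~ N(0, 1/n), pooled
# variance ~ chi-square(df)/df).
mc_dunnett_tail <- function(t_obs, k, n, n0, df, n_draws = 1e5, seed = 1,
                            two_sided = TRUE) {
  withr::with_seed(seed, {
    z0 <- rnorm(n_draws, 0, sqrt(1 / n0))
    zi <- matrix(rnorm(n_draws * k, 0, sqrt(1 / n)), ncol = k)
    s <- sqrt(stats::rchisq(n_draws, df) / df)
    tmat <- (zi - z0) / (s * sqrt(1 / n + 1 / n0))
    stat <- if (two_sided) apply(abs(tmat), 1, max) else apply(tmat, 1, max)
    mean(stat >= if (two_sided) abs(t_obs) else t_obs)
  })
}
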