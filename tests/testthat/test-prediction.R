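fx <- am_fixture()

test_that("endpoint flags follow the strict surface-area threshold", {
  tbl <- tibble::tibble(
    material = c("ZrO2.TODA", "AlOOH", "BaSO4 NM-220", "Pigment Blue 15:1"),
    endpoint = c("LDH", "LDH", "LDH", "TNF"),
    loaec_ug_per_ml = c(45, 90, NA, NA),
    determined = c(TRUE, TRUE, TRUE, FALSE)
  )
  flags <- flag_endpoints(tbl, fx$materials)
  expect_equal(flags$mm2_per_ml, c(5265, 9450, NA, NA))
  expect_equal(flags$flag, c("below_threshold", "above_threshold",
                             "not_significant", "not_determined"))

  # a value of exactly 6000 mm2/mL is not below the threshold
  at <- tibble::tibble(material = "SiO2.naked", endpoint = "LDH",
                       loaec_ug_per_ml = 30) # 30 x 200 = 6000
  expect_equal(flag_endpoints(at, fx$materials)$flag, "above_threshold")

  # classification uses the unrounded dose even when rounding crosses it
  edge <- tibble::tibble(material = "edge", endpoint = "LDH",
                         loaec_ug_per_ml = 59.996)
  mats <- tibble::tibble(name = "edge", bet_m2_per_g = 100) # 5999.6 -> prints 6000
  fl <- flag_endpoints(edge, mats)
  expect_equal(fl$mm2_reported, 6000)
  expect_equal(fl$flag, "below_threshold")

  miss <- tibble::tibble(material = "Corundum", endpoint = "LDH",
                         loaec_ug_per_ml = 90)
  expect_error(flag_endpoints(miss, fx$materials),
               class = "amtox_error_configuration")
})

test_that("two-of-four rule matches brute force over all flag combinations", {
  states <- c("below_threshold", "above_threshold", "not_significant")
  grid <- expand.grid(LDH = states, GLU = states, TNF = states, H2O2 = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    fl <- tibble::tibble(
      material = "m", endpoint = c("LDH", "GLU", "TNF", "H2O2"),
      flag = unlist(grid[i, ])
    )
    out <- classify_in_vitro(fl)
    expected <- if (sum(grid[i, ] == "below_threshold") >= 2) "active" else "passive"
    expect_equal(out$call, expected)
  }
})

test_that("classification tolerates one undetermined endpoint, not two", {
  fl3 <- tibble::tibble(material = "m", endpoint = c("LDH", "GLU", "H2O2"),
                        flag = c("below_threshold", "below_threshold",
                                 "not_significant"))
  expect_equal(classify_in_vitro(fl3)$call, "active")
  fl2 <- fl3[1:2, ]
  expect_error(classify_in_vitro(fl2), class = "amtox_error_insufficient")
})

test_that("classification is invariant to endpoint order and inert flags", {
  fl <- tibble::tibble(
    material = "m", endpoint = c("LDH", "GLU", "TNF", "H2O2"),
    flag = c("below_threshold", "above_threshold", "below_threshold",
             "not_significant")
  )
  out1 <- classify_in_vitro(fl)
  out2 <- classify_in_vitro(fl[c(3, 1, 4, 2), ])
  expect_equal(out1$call, out2$call)
  expect_equal(out1$call, "active")
})

test_that("in vivo categorization applies the 10 mg/m3 rule with bounds", {
  cat <- categorize_in_vivo(fx$stis)
  get <- function(m) cat$in_vivo_category[cat$material == m]
  expect_equal(get("BaSO4 NM-220"), "passive")   # >= 50
  expect_equal(get("CeO2 NM-211"), "active")     # < 0.5
  expect_equal(get("AlOOH"), "passive")          # 3 x 4 = 12 >= 10
  expect_equal(cat$noaec_5day_mg_m3[cat$material == "AlOOH"], 12)
  expect_equal(get("SiO2.naked"), "active")      # 2.5 < 10
  expect_equal(get("Graphite nanoplatelets"), "passive") # >= 10 exactly

  # exactly 10 mg/m3 without findings is passive
  ten <- tibble::tibble(material = "x", noaec_mg_m3 = 10,
                        noaec_bound = "exact", exposure_days = 5)
  expect_equal(categorize_in_vivo(ten)$in_vivo_category, "passive")

  bad <- ten; bad$noaec_mg_m3 <- NA
  expect_error(categorize_in_vivo(bad), class = "amtox_error_data")
})

test_that("cooper_statistics identities hold for random confusion tables", {
  set.seed(12)
  for (i in 1:25) {
    tp <- sample(0:10, 1); fp <- sample(0:10, 1)
    fn <- sample(0:10, 1); tn <- sample(0:10, 1)
    if (tp + fp + fn + tn == 0) next
    pairs <- data.frame(
      in_vitro = rep(c("active", "active", "passive", "passive"),
                     c(tp, fp, fn, tn)),
      in_vivo = rep(c("active", "passive", "active", "passive"),
                    c(tp, fp, fn, tn))
    )
    cs <- cooper_statistics(pairs)
    expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(tp, fp, fn, tn))
    chk <- function(v, num, den) {
      if (den == 0) expect_true(is.na(v)) else expect_equal(v, 100 * num / den)
    }
    chk(cs$sensitivity, tp, tp + fn)
    chk(cs$specificity, tn, tn + fp)
    chk(cs$accuracy, tp + tn, tp + fp + fn + tn)
    chk(cs$ppv, tp, tp + fp)
    chk(cs$npv, tn, tn + fn)
  }
  expect_error(cooper_statistics(data.frame(in_vitro = character(),
                                            in_vivo = character())),
               class = "amtox_error_argument")
})

test_that("an all-correct toy set scores 100 % accuracy", {
  pairs <- data.frame(in_vitro = c("active", "passive"),
                      in_vivo = c("active", "passive"))
  cs <- cooper_statistics(pairs)
  expect_equal(cs$accuracy, 100)
  expect_equal(glance(cs)$accuracy, 100)
})

test_that("prediction model on the packaged LOAEC table reproduces the calls", {
  pred <- run_prediction_model(fx$loaec, fx$materials, fx$stis)

  expect_equal(sum(pred$comparison$in_vitro == "active"), 10)
  wrong <- pred$comparison[pred$comparison$in_vitro != pred$comparison$in_vivo, ]
  expect_equal(wrong$material, "Pigment Blue 15:1")
  expect_equal(wrong$in_vitro, "active") # the single false positive

  # the positive control is classified active but kept out of the concordance
  expect_equal(
    pred$classification$call[pred$classification$material == "Quartz DQ12"],
    "active"
  )
  expect_false("Quartz DQ12" %in% pred$comparison$material)
  expect_equal(nrow(pred$comparison), 20)

  cs <- pred$cooper
  expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(9, 1, 0, 10))
  expect_equal(round_half_up(cs$specificity), 91) # 100 * 10 / 11 = 90.9
})

test_that("raising the threshold never turns an active call passive", {
  for (thr in list(c(3000, 6000), c(6000, 12000))) {
    lo <- run_prediction_model(fx$loaec, fx$materials, fx$stis,
                               threshold_mm2_per_ml = thr[1])
    hi <- run_prediction_model(fx$loaec, fx$materials, fx$stis,
                               threshold_mm2_per_ml = thr[2])
    both <- merge(lo$classification, hi$classification, by = "material")
    expect_false(any(both$call.x == "active" & both$call.y == "passive"))
  }
})

test_that("empty inputs yield empty reports", {
  pred <- run_prediction_model(fx$loaec[0, ], fx$materials, fx$stis)
  expect_equal(nrow(pred$comparison), 0)
  expect_null(pred$cooper)
})

test_that("run_pipeline classifies simulated materials end to end", {
  active_mat <- four_endpoint_scenario("sim-active", bet = 50,
                                       ldh = potent_params(),
                                       tnf = potent_params())
  passive_mat <- four_endpoint_scenario("sim-passive", bet = 50)
  obs <- dplyr::bind_rows(
    simulate_material(active_mat$endpoint_params, seed = 61,
                      material = "sim-active"),
    simulate_material(passive_mat$endpoint_params, seed = 62,
                      material = "sim-passive")
  )
  mats <- tibble::tibble(name = c("sim-active", "sim-passive"),
                         bet_m2_per_g = 50)
  stis <- tibble::tibble(material = c("sim-active", "sim-passive"),
                         noaec_mg_m3 = c(1, 50),
                         noaec_bound = c("exact", "at_least"),
                         exposure_days = 5)
  pred <- run_pipeline(obs, mats, stis)
  calls <- setNames(pred$classification$call, pred$classification$material)
  expect_equal(calls[["sim-active"]], "active")
  expect_equal(calls[["sim-passive"]], "passive")
  expect_equal(pred$cooper$tp + pred$cooper$tn, 2)
})
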