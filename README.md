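# amtox

Hazard pre-screening of (nano)materials with the NR8383 rat alveolar
macrophage (AM) assay. The package turns replicate-level in vitro endpoint
measurements — LDH and β-glucuronidase release, bioactive TNF-α, and
extracellular H₂O₂ — into an *active*/*passive* hazard call per material and
quantifies how well those calls agree with categorizations from rat
short-term inhalation studies (STIS). It is aimed at inhalation
toxicologists and 3Rs-minded screeners who want the whole chain — plate
normalization, LOAEC statistics, dose-metric conversions, decision rule,
concordance — as reproducible, testable code.

## The model

1. **LOAEC determination.** Per material × endpoint, a fixed-effects
   two-way ANOVA (concentration + experiment) pools the residual variance,
   and Dunnett's many-to-one comparison tests each concentration against
   the vehicle control (α = 0.05, two-sided). The in vitro LOAEC is the
   lowest significant concentration.
2. **Surface-area dose metric.** Mass LOAECs (µg/mL) are multiplied by the
   material's BET specific surface area (m²/g); since 1 m²/g = 1 mm²/µg the
   product is the surface-area dose in mm²/mL.
3. **Threshold and the 2-of-4 rule.** An endpoint is flagged when its
   surface-area LOAEC is strictly below 6000 mm²/mL (derived from 4000 µm²
   particle surface per AM; effects above the threshold are attributed to
   cellular overload). A material is **active** iff ≥ 2 of the 4 endpoints
   are flagged.
4. **Concordance.** In vivo truth: active iff the 5-day-equivalent STIS
   NOAEC < 10 mg/m³ (28-day NOAECs are scaled ×4). Agreement is summarized
   with Cooper statistics: sensitivity, specificity, accuracy, PPV, NPV.

The published 20-material evaluation (plus corundum and quartz DQ12
benchmarks) ships as plain-CSV fixtures: material registry with BET areas,
the mean ± SD endpoint grid, the per-endpoint LOAEC table, and the STIS
records.

## Worked example

```r
library(amtox)

fx <- am_fixture("wiemann2016")
pred <- run_prediction_model(fx$loaec, fx$materials, fx$stis)
pred$cooper
#> Cooper statistics (in vivo reference)
#>               vivo active  vivo passive
#> vitro active            9             1
#> vitro passive           0            10
#> sensitivity 100 %, specificity 91 %, accuracy 95 %, PPV 90 %, NPV 100 %
```

All nine in vivo actives are recovered (no false negatives); a single
passive material (the organic pigment Pigment Blue 15:1) is over-predicted,
giving specificity 10/11 = 91 % and accuracy 19/20 = 95 %. Per-endpoint
detail, e.g. for the zinc oxide material:

```r
dplyr::filter(pred$flags, material == "ZnO NM-111")
#>   material   endpoint loaec_ug_per_ml ... mm2_reported flag
#> 1 ZnO NM-111 LDH                  5.6 ...           84 below_threshold
#> 2 ZnO NM-111 GLU                 90   ...         1350 below_threshold
#> 3 ZnO NM-111 TNF                 22.5 ...          338 below_threshold
#> 4 ZnO NM-111 H2O2                NA   ...           NA not_significant
```

Three endpoints sit below 6000 mm²/mL, so the 2-of-4 rule calls the
material active. The statistics stage works on any replicate-level data,
including synthetic runs from the built-in generator:

```r
params <- dose_response_params(baseline = 20, emax = 30, ec50 = 65,
                               hill = 12, sigma = 3)
call_loaec(simulate_endpoint(params, seed = 42))
#> In vitro LOAEC [synthetic, LDH]: 90 ug/mL (alpha = 0.05, two_sided, vs vehicle_control)
#>   concentration_ug_per_ml     n estimate statistic    df p_adj
#> 1                    22.5     9    -2.04     -1.21    38 0.568
#> 2                    45       9    -1.81     -1.07    38 0.664
#> 3                    90       9    27.0      16.0     38 0
#> 4                   180       9    26.3      15.6     38 0
```

A steep ~10σ effect injected at ≥ 90 µg/mL is recovered as a LOAEC of
90 µg/mL. `plot_dose_response()` and `autoplot()` on the result objects
give ggplot2 views of the raw curves and of the threshold plot;
`operating_characteristics()` estimates P(active) for designed scenarios
(e.g. how rarely a null material or a single-endpoint responder is called
active).

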