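# phytoqc

Statistical tooling for multi-compound quality control of herbal
extracts. The package covers the full workflow used to optimize an
ultrasound-assisted extraction (UAE) and validate the chromatographic
assay that quantifies the extract's marker compounds:

* **Box–Behnken designs** (`bbd_design()`) for three process factors,
  with exact coded/actual level conversion;
* **overall desirability** (`compute_desirability()`): each quality index
  is min–max normalized to `d_i ∈ [0, 1]` and the per-run score is the
  geometric mean `OD = (∏ d_i)^(1/n)`, turning a multi-response
  experiment into a single response;
* **response-surface fitting** (`fit_quadratic()`): OLS of the response
  on the coded second-order polynomial
  `Y = β0 + Σ βi xi + Σ βij xi xj + Σ βii xi²`, with the full
  designed-experiment ANOVA (`rsm_anova()`) including drop-one term sums
  of squares and the lack-of-fit / pure-error split from replicated
  center runs;
* **bounded optimization** (`maximize_surface()`) of the fitted surface
  over the coded design cube, with boundary flags and practical rounding
  (`round_to_practice()`);
* **method validation**: calibration fits, LOD/LOQ, replicate RSDs,
  spike recovery (`fit_calibration()`, `lod_loq()`, `rsd()`,
  `recovery_summary()`);
* **quantification**: peak area → concentration → mg/g content, batch
  totals and harvest-period comparison (`area_to_concentration()`,
  `concentration_to_content()`, `batch_summary()`);
* **seeded synthetic data** for every stage — designed-experiment
  responses from a known surface, calibration points, and
  variable-wavelength chromatograms built from Gaussian peaks
  (`simulate_bbd_responses()`, `simulate_chromatogram()`,
  `integrate_peaks()`).

The reference tables of a complete worked example — a 17-run BBD over
methanol–water proportion (50–90%), liquid-to-solid ratio (30–70 mL/g)
and extraction time (20–50 min), plus the eleven-analyte calibration and
24-batch content tables — ship with the package
(`ch_bbd_experiment()`, `ch_calibration_table()`, `ch_content_table()`).

## Worked example

```r
library(phytoqc)

exper <- ch_bbd_experiment()           # 17-run design + OD responses
fit   <- fit_quadratic(exper$design, exper$od)
fit
#> Second-order response surface on coded variables (methanol, ratio, time)
#>    (Intercept)       methanol          ratio           time methanol:ratio
#>         0.8090        -0.2168         0.2018         0.0842         0.0124
#>  methanol:time     ratio:time     methanol^2        ratio^2         time^2
#>         0.0760        -0.0141        -0.3304        -0.0312        -0.0691

rsm_anova(fit)
#>           source     SS df     MS      F      p
#>            model 1.2863  9 0.1429  60.84 0.0000
#>         methanol 0.3758  1 0.3758 160.00 0.0000
#>            ratio 0.3259  1 0.3259 138.76 0.0000
#>             time 0.0568  1 0.0568  24.17 0.0017
#>   methanol:ratio 0.0006  1 0.0006   0.26 0.6246
#>    methanol:time 0.0231  1 0.0231   9.84 0.0165
#>       ratio:time 0.0008  1 0.0008   0.34 0.5802
#>       methanol^2 0.4596  1 0.4596 195.64 0.0000
#>          ratio^2 0.0041  1 0.0041   1.75 0.2277
#>           time^2 0.0201  1 0.0201   8.55 0.0222
#>         residual 0.0164  7 0.0023     NA     NA
#>      lack_of_fit 0.0130  3 0.0043   5.04 0.0760
#>       pure_error 0.0034  4 0.0009     NA     NA
#>  corrected_total 1.3027 16     NA     NA     NA
#> R2 = 0.9874, adjusted R2 = 0.9711

opt <- maximize_surface(fit)           # over the coded cube [-1, 1]^3
opt
#> Surface optimum (maximum stationary form)
#>   coded:   methanol = -0.2678, ratio = 1.0000 [bound], time = 0.3608
#>   actual:  methanol = 64.64, ratio = 70, time = 40.41
#>   predicted response = 1.0196

round_to_practice(opt, c(methanol = 5, time = 5))
#> Surface optimum (maximum stationary form)
#>   coded:   methanol = -0.2500, ratio = 1.0000 [bound], time = 0.3333
#>   actual:  methanol = 65, ratio = 70, time = 40
#>   predicted response = 1.0195
```

Reading the output: the model is strongly significant (F = 60.84,
R² = 0.9874) and adequate (lack-of-fit p = 0.0760 > 0.05); the solvent
proportion dominates (linear F = 160.00, quadratic F = 195.64), and the
solvent × time interaction matters (F = 9.84, p = 0.0165). The fitted
surface peaks at 64.6% methanol, a 70:1 mL/g liquid-to-solid ratio —
**on the boundary** of the studied region, which the result flags — and
40.4 min of sonication. Rounded to operable settings (65%, 70:1,
40 min) the model still predicts OD ≈ 1.02.

The whole chain can also be driven from a config via `run_pipeline()`,
which writes JSON and CSV reports.

## License

MIT.
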