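# nafkinetics

Kinetic analysis of dynamic [18F]sodium fluoride (NaF) PET bone scans, built
to study how far a dynamic knee acquisition can be shortened before the
kinetic parameters degrade.

[18F]NaF uptake in bone follows the irreversible two-tissue (Hawkins)
compartment model: plasma fluoride crosses the capillary wall (K1, k2) and
binds to the hydroxyapatite matrix (k3). The headline quantities are the
plasma clearance to bone `Ki = K1 * k3 / (k2 + k3)`, the perfusion `K1`, and
the extraction fraction `EF = k3 / (k2 + k3)`. The package provides:

- **Forward model** (`tissue_response`, `model_tac`): analytic solution of
  the compartment ODEs by exact piecewise-linear convolution with the
  exponential impulse response, plus blood-volume fraction (vb),
  partial-volume fraction (pvf) and input dispersion (exponential kernel,
  time constant tau).
- **Nonlinear-regression fitting** (`fit_hawkins`, `fit_options`):
  bounded Levenberg-Marquardt (via `minpack.lm`) on frame-averaged model
  TACs, with multi-start, count-statistics inverse-variance weighting, a
  physiologic turnover corridor `k2 + k3` in `[0.1, max_turnover]`, and
  options to fix pvf, vb or tau.
- **Patlak graphical analysis** (`patlak`): slope of the normalized-time
  plot past `t* = 10` min.
- **Image-derived input function** (`run_idif_pipeline`): rule-based artery
  extraction from a 4D volume — early-window PET angiogram, threshold +
  connected-component segmentation, per-slice centered-voxel selection
  (top 10% cap, rise-and-fall gradient check) — validated on a synthetic
  vessel-tube phantom (`build_phantom`) and against venous samples
  (`compare_venous`).
- **Synthetic cohort generator** (`generate_cohort`): Feng-model arterial
  input, stratified regional kinetics (low/medium/high uptake by Ki), and
  Gaussian frame noise with count-statistics variance (decay- and
  duration-scaled).
- **Scan-duration truncation study** (`run_duration_study`): refit every
  region at 20-45 min truncations of both the TAC and the input function,
  report signed normalized errors vs the 50-min reference, overall and per
  uptake stratum, with CSV table output (`write_study_tables`).

## Example

```r
library(nafkinetics)

cohort <- generate_cohort(n_regions = 40, seed = 1)   # 50-min scans, sc = 0.05
study  <- run_duration_study(cohort)                  # ~15 s
print(study)
```

```
Scan-duration study: reference 50 min, durations 20/25/30/35/40/45, 40 regions (0 dropped)
Overall normalized error (mean +/- SD, %):
  20 min: extraction_fraction -8.84+/-21.41, hawkins_Ki -1.87+/-20.50, K1 8.87+/-18.72, patlak_Ki -12.67+/-39.82
  25 min: extraction_fraction -4.53+/-14.88, hawkins_Ki -1.79+/-10.05, K1 4.32+/-12.44, patlak_Ki -3.99+/-20.48
  30 min: extraction_fraction -2.31+/-13.31, hawkins_Ki -0.22+/-7.59, K1 3.38+/-11.15, patlak_Ki -0.59+/-16.58
  35 min: extraction_fraction -2.01+/-8.13, hawkins_Ki -0.34+/-4.23, K1 2.23+/-7.44, patlak_Ki 0.07+/-10.98
  40 min: extraction_fraction -0.58+/-7.20, hawkins_Ki 0.58+/-3.36, K1 1.60+/-6.88, patlak_Ki 2.26+/-9.38
  45 min: extraction_fraction 0.12+/-5.46, hawkins_Ki 0.14+/-2.05, K1 0.25+/-4.70, patlak_Ki 1.23+/-5.72
```

The headline trend: errors shrink steadily with duration; from 30 min on,
every Hawkins-model mean error is within ~3.4% and every Hawkins SD within
~13%. Patlak Ki is noisier because low-uptake regions have reference slopes
near zero, so the *normalized* error denominator is tiny (see the vignette's
limitations section).

Single-region fitting:

```r
region <- cohort$regions[[1]]
fit <- fit_hawkins(region$tac, cohort$aif,
                   fit_options(fix_pvf = TRUE, fix_tau = 0.2))
fit$derived$Ki
```

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "nafkinetics")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

`scripts/acceptance.R` writes the four acceptance targets: `t1` the
worked-example Ki (0.015 x 0.81), and `t2`-`t4` the max mean/SD normalized
errors of the default duration study. With the shipped estimator, `t2`
(max |mean| over 30-45 min) is 3.4% and the 20-min Hawkins-Ki error SD is
20.5%; the Patlak low-uptake spread leaves `t3`/`t4` above their nominal
bounds — analysed in the vignette (`vignettes/shortened-naf-pet.Rmd`).
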