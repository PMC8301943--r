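# mipadt — active dynamic thermography analysis for trigger-point screening

`mipadt` automates the analysis of infrared recordings acquired during the
*minimally invasive procedure* (MIP), an active-dynamic-thermography protocol
used to screen chronic sciatica patients for myofascial trigger points: after
a pre-stimulation thermal-symmetry check, trigger points (or matched sensitive
spots) are dry-needled for 10 minutes while an infrared camera records the
referred-pain zone of the leg, followed by 6 minutes of observation. The
package is for researchers who have (or want to simulate) such recordings —
per-frame temperature matrices plus hand-painted region-of-interest masks —
and need the protocol's two diagnostic parameters as time series, with
group-level statistics.

## The measurements

For each subject and each anatomical ROI (thigh, calf, foot), with the mask
selecting `A_ROI` pixels and `T_px` the temperature of pixel `px`:

- Baseline extrema at the first frame (`t0`):
  `T_max = max T_px`, `T_min = min T_px`, and the percentage of ROI pixels
  attaining each (`A_max`, `A_min`).
- **AURP** (autonomic referred pain area), separately for vasodilatation and
  vasoconstriction, with `T_max`/`T_min` frozen at `t0`:

      AURP↑(t) = 100 · #{px : T_px(t) ≥ T_max − 1.5 °C} / A_ROI
      AURP↓(t) = 100 · #{px : T_px(t) ≤ T_min + 1.5 °C} / A_ROI

- **ΔT_avr** (mean-temperature change):
  `ΔT_avr(t) = mean(T_px(t)) − mean(T_px(t0))` over the ROI.

Recordings shorter than 15 minutes, or with significant limb motion (scored
as the worst frame-to-frame fraction of masked pixels changing by more than
1 °C), are excluded before analysis. Per 30-s timepoint, trigger-point
positive and negative groups are compared with **exact two-tailed
Mann–Whitney U tests** (midrank tie correction; the exact permutation
distribution is computed by a rank-sum convolution, with a Monte-Carlo
fallback and 99% Clopper–Pearson CI for very large designs), and subject-level
summary components (per-region maxima of ΔT_avr and AURP↑) are ranked with
**Firth's bias-reduced logistic regression**, whose Jeffreys-prior penalty
keeps Exp(β) finite even when the groups are completely separated.

A synthetic-cohort generator plants known vasodilatation dynamics (a warm
blob growing inside the thigh ROI over a smooth spatial baseline field, with
per-subject whole-limb drift) so the whole chain is testable without patient
data.

## Worked example

Generate a small synthetic cohort (6 + 6 subjects, 120×160 frames sampled
every 30 s for 16 min, planted thigh response of 1.0 °C over 20% of the ROI),
run the metric and statistics stages, and inspect the end of the thigh
ΔT_avr comparison table:

```r
library(mipadt)

spec <- cohort_spec(n_pos = 6L, n_neg = 6L, frame_shape = c(120L, 160L),
                    sampling_interval_s = 30L, seed = 7L)
cohort  <- generate_cohort(spec)
cleaned <- clean_recordings(cohort$recordings)
series  <- do.call(rbind, lapply(cleaned$retained, compute_metric_series,
                                 region = "THIGH"))
attr(series, "analysis_interval_s") <- 30L
cmp <- run_full_comparison(series, metrics = "delta_tavr_c",
                           firth_components = "THIGH_delta_tavr_max",
                           n_mc = 2000L, seed = 7L)
tail(cmp$tests[, c("phase", "time_s", "mean_pos", "sd_pos",
                   "mean_neg", "sd_neg", "p_mc", "p")], 4)
#>          phase time_s mean_pos    sd_pos   mean_neg    sd_neg       p_mc          p
#> 30 observation    870 1.158832 0.6467939 -0.3864357 0.8358698 0.01249375 0.01515152
#> 31 observation    900 1.200642 0.6694554 -0.3995252 0.8650016 0.01399300 0.01515152
#> 32 observation    930 1.206852 0.6918675 -0.4117244 0.8925306 0.01499250 0.01515152
#> 33 observation    960 1.213785 0.7131988 -0.4250243 0.9220624 0.01449275 0.01515152

print(cmp$firth)
#> Firth bias-reduced logistic regression (n = 12, 6 iterations)
#>                  term   beta exp_beta       p
#>           (Intercept) -1.328    0.265      NA
#>  THIGH_delta_tavr_max  1.960    7.100 0.02768
```

Reading the output: by the end of the observation phase the positive group's
thigh ΔT_avr has risen ~1.2 °C (planted: 1.0 °C plus this cohort's drift
draw) while the negative group hovers around zero; the exact per-timepoint
Mann–Whitney p (`p`) is ~0.015, with the Monte-Carlo estimate (`p_mc`) and
its 99% CI agreeing. The Firth odds ratio Exp(β) = 7.1 per °C of peak
ΔT_avr says higher peak warming strongly favours trigger-point-positive
classification.

For a file-based workflow, `generate_cohort(spec, dir = "cohort/")` writes
frame text files, BMP masks and a YAML manifest, and
`run_pipeline(default_config(manifest = "cohort/manifest.yaml", out_dir = "out/"))`
produces the full bundle (`metrics.csv`, `comparison.csv`, `firth.json`,
`exclusions.csv`, `run_metadata.json`). The same is available from a shell
via `Rscript inst/cli/mipadt.R {synth|metrics|compare|all} ...`.

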