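---
title: "Methods: quantifying the autonomic response in MIP thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the autonomic response in MIP thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipadt)
```

## The procedure and its two parameters

The minimally invasive procedure (MIP) is an active-dynamic-thermography
protocol: a pre-stimulation symmetry check, ten minutes of noxious
dry-needling stimulation of gluteal trigger points (or matched sensitive
spots in controls), and six minutes of further infrared observation of the
leg, the presumed referred-pain zone. The working hypothesis is that an
active trigger point amplifies the autonomic vasomotor response in its
referred-pain zone, visible as a growing warm (vasodilatation) or cool
(vasoconstriction) area and as a rise in the region's mean temperature.

`mipadt` computes, per subject and anatomical ROI (thigh, calf, foot), the
two diagnostic parameters on every recorded frame:

* **AURP↑ / AURP↓** — the percentage of ROI pixels within a 1.5 °C band of
  the *baseline* extremum: `T ≥ T_max − 1.5` for vasodilatation and
  `T ≤ T_min + 1.5` for vasoconstriction, with `T_max`, `T_min` taken from
  the first frame and never recomputed. Freezing the extrema makes the bands
  an absolute yardstick: any later warming can only move pixels into the
  upper band. The band comparisons are inclusive, and both percentages are
  nonzero at `t0` by construction (the extremum pixels themselves qualify);
  when the baseline ROI range is ≤ 3 °C the two bands overlap and their sum
  exceeds 100% — arithmetic of overlapping bands, not an error.
* **ΔT_avr** — the ROI's mean temperature at `t` minus its mean at `t0`;
  exactly 0 at `t0`, and shifted by exactly `c` by a uniform `+c` warming.

The area quantities count *pixels* (indicator sums over the 0/1 mask), and
percentages are relative to the ROI area `A_ROI`; all pixels tied at an
extremum count toward `A_min`/`A_max`.

Temperatures are rounded to one decimal place at ingest — the precision of
the camera export — and every downstream statistic operates on the rounded
values, so 0.05 °C is the natural quantum below which differences are not
meaningful.

## Masks and the strict-255 rule

ROIs are painted by hand on a BMP copy of a thermogram; no automatic
anatomical segmentation is attempted (limb size and pose vary too much
between patients). The mask pipeline converts RGB to 8-bit luminance
(`0.299 R + 0.587 G + 0.114 B`, rounded half-away-from-zero — the
coefficients sum to 1, so neutral gray survives the round trip exactly) and
keeps *only* pixels at grayscale 255. The rule is deliberately categorical:
mask authors must paint with pure white, and anti-aliased edge pixels
(254 and below) are trimmed. No hole-filling or connected-component
filtering is applied — the contract is purely pixelwise, so disjoint painted
blobs all count.

## Cleaning rules

Before analysis, recordings are dropped when

* shorter than 15 minutes (`min_duration_s = 900`) — the camera-error rule;
* the limb moved: the *motion score* is the worst frame-to-frame fraction of
  masked pixels whose absolute change exceeds `motion_step_c = 1 °C`; scores
  above `motion_threshold = 0.2` exclude the recording. The step/threshold
  pair was chosen once so that slow physiologic drift (≪ 1 °C per 3-s frame)
  and the gradual growth of a genuine vasodilatation area (a fraction of a
  percent of the ROI per frame) can never trigger it, while a limb
  translation of a few pixels flips a large fraction of masked pixels in a
  single step and is caught reliably;
* flagged manually in the manifest (reason `"manual"`).

The pre-stimulation symmetry check compares the pain side's ROI mean against
the contralateral side and fails only when the pain side is colder by
*strictly more than* 0.5 °C (a sign of neuropathic pain); a deficit of
exactly 0.5 °C passes. The check takes explicit frames, leaving the choice
of pre-stimulation frames to the operator.

## Group statistics

Per analysis timepoint (every 30 s), region and metric, the groups are
compared with the exact two-tailed Mann–Whitney U test using midranks for
ties. The exact two-sided p is the permutation-distribution probability of a
deviation of U from `n₁n₂/2` at least as large as observed. Rather than
enumerating the `C(n, n₁)` assignments directly, the distribution of the
rank sum is built by convolution over integer scores (midranks are
half-integers, so doubling them yields integers) — exact for any tie
pattern, and fast enough that the 20 + 20 design is handled exactly. A
Monte-Carlo permutation estimate with a 99% Clopper–Pearson CI is reported
alongside (it fills the results table's CI column, mirroring how commercial
packages report Monte-Carlo exact tests), and the tie-corrected normal
approximation is kept as a diagnostic. Constant pooled data yield p = 1 by
convention, flagged as degenerate. The per-timepoint p values are reported
uncorrected, as is conventional for this screening read-out; a Holm-adjusted
column is emitted for transparency but not used for the headline pattern.

Subject-level components — by default the five per-region maxima
`THIGH_delta_tavr_max`, `THIGH_aurp_up_max`, `CALF_delta_tavr_max`,
`CALF_aurp_up_max`, `FOOT_aurp_up_max`; the set is configurable — enter a
Firth bias-reduced logistic regression of group membership. Firth's penalty
(half the log-determinant of the Fisher information, the Jeffreys prior)
keeps estimates finite under the complete separation that small diagnostic
cohorts often exhibit. Fitting is Newton scoring with the modified score
`U*_j = Σ (y_i − p_i + h_i(½ − p_i)) x_ij` and step-halving on the penalized
log-likelihood; per-coefficient p values are penalized likelihood-ratio
tests (refit with the coefficient pinned at zero), the standard
recommendation for Firth fits, rather than Wald tests. Components are kept
in their natural units (°C, percentage points), so odds ratios are per unit;
on strongly separated synthetic cohorts Exp(β) can be numerically huge while
remaining finite — that is the expected behaviour, not a failure.

## The synthetic cohort

Patient recordings are not distributable, so the generator emulates the
*statistical* structure the analysis assumes — no bioheat modelling:

* a smooth spatial baseline field: iid Gaussian knots (SD
  `spatial_noise_sd_c = 1.0 °C`) every 4 px, bilinearly interpolated around a
  mean skin temperature of 32 °C. This makes `T_max`/`T_min` non-degenerate
  and gives the AURP bands a realistic baseline floor;
* per-frame iid sensor noise (`sensor_noise_sd_c = 0.05 °C`, under the
  rounding quantum);
* a per-subject whole-limb linear drift whose final value has SD 0.7 °C
  (positive group) / 0.8 °C (negative group) — the between-subject
  dispersion of final ΔT_avr;
* for positive subjects, a warm blob growing outward from the thigh ROI
  centroid: its area ramps linearly from `onset_s = 0` to
  `plateau_s = 900 s` up to `blob_fraction = 0.2` of the ROI at constant
  amplitude `peak_delta_c / blob_fraction = 5 °C`, so the planted ROI-mean
  rise follows `1.0 °C × ramp(t)` and the planted vasodilatation area
  reaches 20%. The plateau extends past the 10-minute stimulation, matching
  the observation that the response keeps developing after the noxious
  stimulus ends. Negative subjects receive drift and noise only.

Defaults describe a 20 + 20 cohort recorded every 3 s for 16 min on 240×320
frames. All draws flow from one master seed through a per-subject counter
scheme, so a subject's data are reproducible independently of cohort order,
and a sparse `times` argument (e.g. `c(0, 960)`) generates only the frames
an experiment needs.

What the generator does **not** model: within-subject temporal
autocorrelation of the vasomotor signal (an AR(1)-like knob could be added,
but no realism claim could back a default), anatomical temperature
gradients, camera fixed-pattern noise, or motion other than the planted
translations used to exercise the cleaning rule. Passing tests therefore
demonstrate correctness of the computations and calibration of the tests
under this structure, not clinical validity on real recordings.

### Resolution and problem sizes

The spatial field's 4-px correlation length fixes patch size in pixels, so
coarser frames contain fewer independent patches inside the ROI, the
baseline maximum sits lower, and the 1.5 °C band covers a larger area
fraction: AURP percentages inflate as resolution shrinks (at 240×320 the
baseline band is a few percent; at 24×32 it is most of the ROI). ΔT_avr, a
ROI mean, is resolution-invariant, which is why the calibration experiments
read it. The shipped experiments use 120×160 frames on a 30-s grid for the
end-to-end cohort run and 24×32 two-frame recordings for the replicated
calibration studies (400 null replicates, 200 effect replicates) — sizes
chosen to keep the full validation suite runnable on a laptop in about a
minute while leaving every conclusion unchanged at larger sizes.

## Numerical choices and edge cases

* Rounding: one decimal at ingest, halves away from zero (`round_temp`);
  8-bit luminance likewise rounds half-away and clamps to [0, 255].
* Exact-test tie handling: midranks; the two-sided region is defined by
  `|U − n₁n₂/2| ≥ |u_obs − n₁n₂/2| − 1e-9` (the permutation distribution of
  U with midranks is symmetric about `n₁n₂/2`).
* Firth convergence: Newton with step-halving, tolerance 1e-10 on step and
  penalized log-likelihood change, 100-iteration cap with a hard error on
  failure; constant predictors are dropped with a message (the intercept-only
  penalized fit has the closed form `p̂ = (Σy + ½)/(n + 1)`).
* Frame text dialect: whitespace, comma or semicolon delimiters; decimal
  commas are recognized (a comma inside a single numeric token) and
  normalized. Malformed values and shape mismatches fail with row/column
  coordinates.
* Timestamps come from manifest order × sampling interval, never from file
  names.
* Empty masks, single-class outcomes, empty samples, and single-group
  cohorts are hard errors naming the offending subject/region/group.

## Known limitations

* The motion score detects *thermal-structure* displacement; a perfectly
  uniform limb could move undetected (real thermograms are never uniform).
* The symmetry check is exposed as an operation on explicit frame pairs; it
  is not wired into `run_pipeline`, because contralateral recordings are a
  separate acquisition.
* The Firth component set labelled "five components" is a configuration
  default, not a claim about any particular clinical model.
* Monte-Carlo p values depend on the configured seed; the exact path is
  deterministic and preferred whenever the pooled sample is ≤ 60.
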