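---
title: "Retention-time-window semi-quantification: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention-time-window semi-quantification: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntaquant)
```

## The model

In negative-mode electrospray, a compound's signal response per unit
concentration (its calibration gradient, counts per ppm) is governed by
ionization efficiency, which varies over orders of magnitude with
acidity, charge stabilization and molecular size. Quantifying the
thousands of unidentified compounds a nontarget workflow detects is
therefore impossible with any single response factor.

The approach implemented here assumes that compounds eluting close
together in reversed-phase chromatography are more alike in the
properties that drive ionization than the compound population at large,
so the *distribution* of gradients among authentic standards eluting in
the same retention-time window is a usable model for the gradient of an
unknown eluting there. The point estimate for an unknown with peak area
$A$ in window $w$ is

$$\hat{c} = A / \mathrm{median}\{g_i : i \in w\},$$

and the envelope $(A/\max g, A/Q_3 g, A/\mathrm{median}\, g, A/Q_1 g,
A/\min g)$ spans the concentrations the unknown would have if it
ionized like any member of the window. Note the deliberate reversal:
the *upper*-quartile gradient produces the *lower*-quartile
concentration because concentration is area over gradient; envelope
fields are named by concentration ordering so
`conc_min <= conc_lq <= conc_median <= conc_uq <= conc_max` always
holds. Compounds identified to Schymanski Level 1 bypass the window and
use their own standard's gradient (a collapsed envelope); CHOS
organosulfates are scaled with a single surrogate-standard gradient, as
no window family exists for that class.

Calibration curves are ordinary least squares of signal on
concentration over all replicate points — the full error structure,
rather than replicate means — without forcing the line through the
origin. The fitted intercept is retained for reporting but ignored in
scaling: inversion uses the gradient alone.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| CHO window scheme | 14 × 1 min (0–14) + 3 × 2 min (14–20) | min | 17 windows; 1-min resolution where standards are dense, 2-min where sparse |
| CHON window scheme | 8 windows of 2–3 min (0–20) | min | fewer nitroaromatic standards force wider windows |
| blank ratio threshold | 10 | — | sample/blank area ratio below which a matched feature is background |
| S/N threshold | 3 | — | features must strictly exceed it |
| m/z match tolerance | 5 | ppm | typical Orbitrap mass accuracy for sample/blank and cross-polarity matching |
| rt match / duplicate tolerance | 0.1 | min | typical alignment jitter |
| R² floor for usable curves | 0.8 | — | linearity floor, as in standard-addition acceptance practice |
| unit conversion factor | 1 | (µg m⁻³)/ppm | extract volume over sampled air volume; identity keeps results in extract ppm |
| factor-of-k band | k = 2, inclusive | — | a prediction error of exactly 0.5 or 2 counts as within the band |

The 17-window CHO default deserves a note: the widths stated for the
scheme (1-min windows to 14 min, 2-min windows to 20 min) only produce
seventeen windows if the 2-min bins span 14–20 min, so that is the
built-in scheme. CHON window boundaries are configuration, not code;
the built-in eight-window scheme (breaks at 0, 2, 4, 6, 8, 11, 14, 17,
20 min) realizes the stated count and width range.

## Numerical choices

* **Quartile convention.** Windows can hold as few as two standards,
  where quantile estimators genuinely diverge. We fix linear
  interpolation between order statistics (`stats::quantile` type 7) and
  use it everywhere: window statistics, abundance IQRs. With one
  member, all five statistics coincide.
* **Window membership.** Half-open `[start, end)` with the final window
  of each class closed at its end, so every retention time in the
  covered range maps to exactly one window and a standard at a shared
  boundary goes to the later window.
* **Degenerate calibration inputs.** Fewer than two distinct
  concentration levels is an error; a non-positive slope or an R² below
  the floor flags the curve unusable and excludes it from window
  membership with a warning rather than failing a run.
* **Zero blank area.** A feature matched to a blank entry with zero
  area is kept (ratio treated as infinite): absence of blank signal
  cannot justify removal.
* **Thresholds are strict as printed.** Ratio < 10 removes; S/N must
  strictly exceed 3 (a boundary value of exactly 3 is removed);
  elemental-ratio bounds are exclusive on both sides.
* **Polarity ties.** Equal areas in both modes exclude the feature from
  negative-mode quantification — strict reading of "larger peak area".
* **Duplicate collapsing.** "Duplicated data" has no canonical
  operational definition; we collapse features sharing a best formula
  within the retention-time tolerance greedily by descending peak area,
  so isomers at distinct retention times always survive.
* **Out-of-window features.** Unquantified with a recorded reason by
  default; a nearest-window policy exists behind a flag but
  extrapolating scaling factors is not the conservative choice.
* **Per-compound aggregation.** Validation reports both raw per-sample
  ratios and per-compound ratios of arithmetic-mean concentrations,
  since multi-sample compounds can enter either way.

## The synthetic data generator

`fixture_config()` + `make_standard_library()` + `make_sample()`
emulate the study conditions the method targets: five standards per
window with gradients drawn log-uniformly over four orders of magnitude
(the widest within-window spread observed among real standards;
log-normal draws around window medians, σ = 0.3 in log10, model
the unknowns), 7-level × 3-replicate calibration series, samples of a
few hundred features dominated by CHO with minority CHON/CHOS, and
controlled injections of every pathology the post-processing stage
must handle — blank contamination at sample/blank ratios straddling 10,
sub-threshold signal-to-noise, exclusion-list species, alignment
duplicates, cross-polarity twins. Every generated parameter lands in a
truth table, so recovery can be asserted exactly: with noiseless
calibration and unknowns placed on their window medians, the pipeline's
prediction errors equal 1 to machine precision.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: matrix effects (signal
suppression/enhancement by co-extracted material), retention-time drift
between runs, formula misassignment (generated candidates are correct
by construction), correlated gradient structure within windows beyond
the configured class offsets, and chromatographic peak-shape artifacts.
On real extracts the prediction-error distribution is driven by how
well each window's standards represent the sample's chemistry, which
only authentic-standard validation can establish.

Test and acceptance runs use libraries of ~126 standards (25 windows ×
5 + 1 CHOS surrogate) and samples of 100–250 features; these sizes make
the statistics stable while keeping the whole suite fast.

## Composition summaries

Class abundance is computed five times — once per gradient statistic —
by recomputing every feature's concentration under that statistic,
summing per class over the quantified classes (CHO, CHON, CHOS;
"other" is reported separately) and normalizing to percent. The
method's uncertainty on a class's share is the width of its
interquartile band, `|uq_pct − lq_pct|`: because each scenario is
renormalized, a class's share under the upper-quartile scenario is not
guaranteed to exceed its share under the lower-quartile one, so the
absolute width is the meaningful quantity. Across-sample means ± sd of
the per-sample percentages are reported alongside the per-sample method
IQR — the two uncertainties are distinct and labeled separately. Bulk
descriptors (concentration-weighted mean formula, O:C, H:C) come in a
peak-area-weighted variant as well, since contrasting the two
weightings is exactly how one sees peak area misstate composition:
when a minority class ionizes efficiently, its peak-area share
overstates its mass share.

## Known limitations

* Negative-mode only; positive-mode quantification would need its own
  standard set and window schemes.
* CHOS rests on a single surrogate gradient; CHONS and halogenated
  species are not quantified.
* The matrix-effect and recovery helpers summarize externally measured
  standard-addition and spike data; the package does not model matrix
  effects.
* Comparison against ionization-efficiency predictive models consumes
  externally supplied predicted concentrations; no such model is
  implemented or trained here.
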