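---
title: "Quantifying receptor localization across dorsal horn regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor localization across dorsal horn regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhquant)
```

## The measurement problem

Immunohistochemical studies of receptor distribution in the spinal dorsal
horn ask a deceptively simple question: is the target protein enriched in
the superficial dorsal horn (SDH, laminae I–II, the main nociceptive
processing region) relative to the deeper dorsal horn (DDH, laminae
III–VI)? The standard workflow images a two-channel section — the target
(e.g. the CB1 cannabinoid receptor, amplified cy3 signal) alongside a
landmark channel (CGRP, which labels peptidergic C-fiber terminals and so
delineates the SDH) — outlines the SDH where marker staining is maximal,
takes the rest of the dorsal horn as the DDH, and measures each region's
optical density (O.D.): integrated fluorescence intensity divided by
region area. Each region's O.D. is normalized to a square of white matter
in the dorsal column, where target fluorescence should be minimal, and the
per-subject endpoint is the SDH/DDH ratio

$$R \;=\; \frac{\mathrm{O.D.}_{\mathrm{SDH}}/\mathrm{O.D.}_{\mathrm{bg}}}
              {\mathrm{O.D.}_{\mathrm{DDH}}/\mathrm{O.D.}_{\mathrm{bg}}},$$

a dimensionless localization index ($R = 1$ means no regional preference).
`dhquant` reimplements this pipeline as tested, scriptable code, together
with the small-cohort statistical battery such studies use and the
single-cell RNA-seq summarizer that complements the protein-level picture
with transcript-level (`CNR1`/`CNR2`) evidence.

Because real stained tissue is not redistributable, the package ships
generators for synthetic section phantoms and clustered count matrices
with the statistical structure the analysis assumes. Every downstream
stage is exercised against those generators' ground truth.

## The section phantom

`phantom_params()` describes a stylized transverse section: the dorsal
horn is a half-elliptical dome; its curved dorsal surface carries a
superficial band (the SDH analog) of configurable thickness; everything
outside the dome is white matter. The geometry is deliberately not
anatomically faithful — laminae, mediolateral structure and the optics of
a confocal stack (point-spread function, z-stacks, tiling) are out of
scope — because the downstream measurement only consumes region-mean
contrasts.

The target channel has expectation $s\,I_0\rho$ inside the band,
$s\,I_0$ in the remaining dome and $s\,I_0\beta$ outside, where:

* $I_0$ (`base_intensity`, default 100 a.u.) sets the deep-dorsal-horn
  level;
* $\rho$ (`rho`, dimensionless) is the ground-truth SDH/DDH contrast the
  pipeline estimates. Defaults follow the contrast scale reported for rat
  tissue (≈1.8); human-scale simulations use ≈1.5;
* $\beta$ (`background_frac`, default 0.2) is the white-matter fraction;
* $s$ is a multiplicative subject effect, lognormal with unit mean and
  log-sd `subject_sd` (default 0.10), shared across a subject's slides; a
  per-slide lognormal effect (`replicate_sd`, default 0.05) models
  staining-batch variation. Neither has a published estimate, so both are
  config-exposed; their defaults are ordinary inter-animal and
  slide-to-slide scales for quantitative IHC. Because both are
  multiplicative over the whole image, background normalization cancels
  them — and the test suite verifies that it does.

Noise is Poisson shot noise (`poisson_gain`, photons per intensity unit;
default 1, giving SNR ≈ 10 in the DDH) plus additive Gaussian read noise
(`read_noise_sd`, default 5 a.u.), the standard fluorescence-camera model;
values are clamped at zero afterwards. The marker channel is `cgrp_peak`
inside the band and zero elsewhere, under the same noise. With all noise
and variance parameters at zero, region means equal their closed-form
targets exactly, which the tests assert to machine precision.

All randomness flows from one master seed: `generate_cohort()` splits a
per-subject stream (for the subject effect) and per-section streams (for
replicate effects and pixel noise) with the multiplicative-congruential
scheme in `split_seed()`, so any one section can be regenerated without
replaying the cohort.

For the count matrices, `counts_spec()` takes per-gene, per-cluster
negative-binomial means and a dispersion (NB size; `Inf` gives Poisson),
the standard overdispersion model for single-cell/nucleus counts. The
bundled `default_counts_spec()` places a `Cnr1`-analog at 10× higher mean
in clusters annotated to superficial laminae and a `Cnr2`-analog at a
near-zero mean everywhere, the qualitative pattern the summarizer should
resolve.

## Region derivation

The published workflow draws the SDH contour by hand where marker staining
is maximal. `segment_sdh()` replaces this with a deterministic, auditable
chain: Gaussian smoothing (`smooth_sigma`, default 2 px), a threshold
(Otsu's bimodal split by default, making the result invariant to global
intensity rescaling; a fixed threshold can be configured for phantoms),
removal of components below `min_area`, selection of the largest connected
component, and hole filling. `derive_ddh()` is set subtraction from the
dorsal-horn contour, and `place_background_box()` slides an $s \times s$
box over every position clear of the (margin-dilated) dorsal horn and
keeps the one minimizing mean target intensity — the algorithmic reading
of "where there should be minimal fluorescence" — breaking exact ties
lexicographically by (row, column). Hand-drawn contours from a real-tissue
workflow enter through `load_manual_rois()` (PNG masks or polygon CSVs);
pixels claimed by both SDH and DDH go to the SDH with a warning.

Two numerical consequences are worth knowing. First, the minimum-mean box
placement is biased slightly low in noisy images (it selects a favorable
noise realization); this inflates both normalized region values by the
same factor and cancels exactly in the ratio $R$, which is the endpoint.
Second, segmentation errors concentrate in a ~1-pixel boundary ring, where
the band meets low-intensity white matter on one side and the DDH on the
other; this biases measured $R$ a percent or two below $\rho$ at default
noise. The recovery tests therefore check the full segmentation pipeline
to 5% and reserve exactness claims for ground-truth regions with noise
off.

## Aggregation and the statistical battery

Per-slide normalized SDH and DDH values are averaged across each subject's
technical replicates (triplicate in rat-like designs, duplicate in
human-like ones) and the ratio is taken of the means. The alternative
order — averaging per-slide ratios — differs in general; it is reported
alongside (`ratio_slidewise`) and can be promoted to the primary endpoint
via the `ratio_variant` config switch. A subject missing a slide is kept
with a lowered replicate count and a warning rather than dropped.

Inference mirrors small-cohort practice:

* `assumption_checks()` gates on Levene's test (mean-centered variant —
  no variant is conventionally specified, and centering on the mean is the
  original form) and per-group Shapiro-Wilk, both at $\alpha = 0.05$. A
  constant group fails normality by convention.
* Independent comparisons use one-way ANOVA when the gate passes and the
  Mann-Whitney U test otherwise; paired comparisons use the Wilcoxon
  signed-rank test. The battery defines no paired parametric branch, so a
  paired comparison with a passing gate still runs as Wilcoxon, with a
  note in the result.
* Both rank tests are implemented in-package in two modes. Exact mode
  enumerates the full permutation distribution ($2^n$ sign assignments up
  to $n = 25$; $\binom{n_1+n_2}{n_1}$ labelings up to $n_1+n_2 = 14$) and
  doubles the smaller tail, capping at 1; beyond the caps it falls back to
  the asymptotic mode with a note. Asymptotic mode uses the normal
  approximation with tie-corrected variance and **no continuity
  correction**, with zero differences **discarded** before ranking. That
  pair of conventions is deliberate: it is the variant that yields
  two-sided $p = .028$ at $n = 6$ and $p = .018$ at $n = 7$ when every
  pair moves the same way — the values a reader of a small paired IHC
  cohort analyzed in SPSS will recognize. Degenerate variance (all values
  tied) returns $p = 1$ rather than an error.
* No multiple-testing correction is applied anywhere; each comparison is
  reported at its raw $\alpha$, matching field practice for these designs.

Two-factor questions (sex × species) use the aligned rank transform (ART)
ANOVA, implemented in full. For each effect, responses are aligned by
subtracting cell means and adding back the estimated effect of interest
(computed from unweighted marginal means of the cell means), ranked with
average ranks on ties, and submitted to a full two-way factorial ANOVA on
the ranks, from which only the target effect's row is reported. Balanced
layouts use closed-form sums of squares; unbalanced ones (e.g. 6 rats vs
7 humans per sex) fall back to a Type III fit with sum-to-zero contrasts.
Every run records two diagnostics: the aligned-response sums (zero for a
balanced complete layout, up to floating point) and the F values of the
non-target effects in an ANOVA on the aligned but unranked responses
(≈0 when alignment is correct). A 2×2 null simulation in the test suite
(2000 replicates) checks that each effect's type-I error stays within
[0.03, 0.07] at $\alpha = .05$.

## Expression summarization

`cpm_normalize()` scales each cell to counts-per-million (so every
retained cell sums to $10^6$; zero-total cells are dropped with a
warning; all genes stay in the denominator). Clusters are pooled via
laminar annotations: `parse_laminae()` turns strings like
`"laminae III-VI"` into tokens, and the default `grouping_scheme()` sends
laminae I, II and IIo to the SDH pool and II, IIi and III–VI to the DDH
pool — so a lamina II cluster legitimately sits in both, the overlap the
pooling convention itself implies — plus a `DH` group holding every cell
once. Per (gene, group), `dot_plot_table()` reports the average CPM, the
percent of cells with nonzero counts, and a color value: $\log_{10}$(CPM
+ 1) standardized **across that gene's displayed groups** using the
population standard deviation. The standardization scope is a genuine
choice (per gene within one panel is what makes colors comparable along a
row); the population SD makes the two-group case exactly ±1; a single
group or zero variance maps to z = 0 by convention. `render_dot_plot()`
draws the conventional grid — dot size ∝ percent expressed, diverging
color for z.

## Problem sizes and what the tests do(n't) show

The bundled checks run at desk scale: 160×160-pixel phantoms, cohorts of
6–7 subjects per cell with 2–3 replicates, 20 master seeds for recovery
(ratio within 5% of $\rho$ at default noise, exact with noise off), 10
seeds for segmentation quality (Dice ≥ 0.90 against ground truth), 2000
replicates for the ART null, and a hand-computed 3-gene × 8-cell oracle
for the summarizer. These sizes make the full suite complete in about a
minute while leaving Monte-Carlo margins comfortably inside the asserted
tolerances.

Passing them shows the arithmetic, the conventions and the statistical
machinery are right; it does not certify performance on real tissue.
The phantoms have no anatomy, no optics, no staining artifacts, and their
marker band is cleanly bimodal, so Otsu thresholding is easy; published
ratios from real sections (e.g. ≈1.8 in rats, ≈1.5 in humans) reflect
biology plus all of those nuisances and are not desk-reproducible.
Real-data ART and ratio-comparison p-values are likewise data-dependent
and out of scope; only the structural small-$n$ signed-rank values are
pinned.

## Known limitations

* The SDH band phantom wraps the whole dome boundary, including its
  ventral corners; real CGRP bands cap the dorsal surface only.
* Automatic background placement assumes some admissible white-matter
  box exists; sections whose dorsal horn fills the frame need
  user-specified coordinates.
* ART alignment uses unweighted marginal means; under severe imbalance
  its aligned sums no longer vanish and the Type III fallback carries the
  inference.
* The exact-mode caps are deliberate desk-scale bounds, not statistical
  limits; raise them only with the memory cost of $2^n$ enumeration in
  mind.
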