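---
title: "Refraction-derived corneal power for post-refractive IOL calculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refraction-derived corneal power for post-refractive IOL calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolpost)
```

## The optical model

The package models the pseudophakic eye with the Haigis thin-lens vergence
formula: two refracting elements — the cornea, with total power $D_c$
diopters, and the IOL, with power $P$ — separated by the effective lens
position (ELP) $d = a_0 + a_1 \cdot \mathrm{ACD} + a_2 \cdot \mathrm{AL}$
(millimetres), in a medium of refractive index $n$. With lengths in metres,
the corneal-plane power required to focus $P$ on the retina of an eye of
axial length $L$ is

$$z = \frac{n}{d + \dfrac{n}{n/(L-d) - P}},$$

the corneal-plane refraction is $R_c = z - D_c$, and the spectacle-plane
refraction at vertex distance $d_x$ is $R_x = R_c / (1 + R_c d_x)$.

Every public operation is an algebraic rearrangement of this one chain:

* `predict_refraction()` — $R_x$ given $(D_c, P, L, d)$;
* `iol_power_for_target()` — $P$ given a target $R_x$;
* `back_calculated_k()` — $D_c$ given an *achieved* $R_x$ and the implanted
  $P$. This is the refraction-derived K (Krd): the corneal power that makes
  the formula's prediction agree exactly with what the eye actually did.

Because the Haigis ELP uses ACD and AL only (no K term), all three
inversions are closed-form; no iteration is involved anywhere. The sign
convention for the corneal/spectacle plane conversion is not trusted to
formula transcription: the test suite enforces the round-trip identities
(`predict_refraction(iol_power_for_target(t)) == t` and
back-calculation recovering a simulating K, both to $10^{-9}$ D) as the
normative contract, which eliminates the classic $\pm$ vertex-distance bug.
The closed forms are additionally checked against an independent
surface-by-surface vergence trace (root-finding, no shared algebra) to
$10^{-6}$ D.

An ambiguity worth recording: clinical descriptions of the back-calculation
speak of minimising the difference between target and actual refraction via
device software whose algorithm is unpublished. This package defines the
inversion through the standard Haigis formula, solving for the K at which
the *predicted* refraction equals the *achieved* postoperative spherical
equivalent; the round-trip identity is what makes that definition testable.

## Why a corrected K is needed

Myopic laser ablation flattens the anterior cornea and leaves the posterior
surface untouched, so keratometry based on a fixed anterior/posterior ratio
overestimates corneal power and IOL formulas under-power the lens — the
hyperopic surprise. Scheimpflug total corneal refractive power (TCRP, ray
traced) and total refractive power (TRP) in the central 4.0 mm zone measure
both surfaces, and are entered into the vergence formula *as-is* by default
(`corneal_power(mode = "direct")`). A `reindex` mode
($D_c' = D_c \cdot 331.5/337.5$) is provided because the classical Haigis
convention derives corneal power from radius with index 1.3315 while
standard keratometry uses 1.3375; `direct` is the default because
total-power maps are already physical powers, not index-converted radii.

Even total corneal power benefits from an empirical calibration. Regressing
the back-calculated Krd on the measured K over a calibration cohort yields a
correction line applied to future eyes before the formula
(`apply_krd()`). The package ships the published calibrations as frozen
presets —

* TCRP 4 mm: $K_{rd} = 0.989\,K + 0.179$ (Pearson r = 0.873, n = 50),
* TRP 4 mm: $K_{rd} = 0.974\,K + 0.882$ (r = 0.898, n = 50),

via `krd_paper_regression()` — and re-derives such calibrations from any
cohort with `calibrate_from_cohort()` (plain unweighted OLS, no outlier
rejection; per-point weights are accepted for forward compatibility, and a
fitted calibration never overwrites the shipped presets). Note that the
published mean Krd.TCRP (38.74 D) is not exactly the preset line evaluated
at the published mean K (39.24 D gives 38.99 D); this is coefficient
rounding in the source report. The printed coefficients are treated as
normative and no reconciliation is attempted.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `a0, a1, a2` | — | user-supplied | lens-model-specific ELP constants; never hard-coded as truth. `example_iol_constants()` ships a generic monofocal triple (1.513, 0.4, 0.1, from ACD constant 5.20) for simulation only |
| `n_aqueous` | — | 1.336 | aqueous/vitreous index used in all vergence steps |
| `vertex_distance` | mm | 12 | plane of the manifest refraction; source reports rarely state it, 12 mm is the convention, and it is exposed in the configuration rather than buried |
| `mode` | — | `"direct"` | keratometric handling of TCRP/TRP values (above) |
| IOL step | D | 0.5 | clinical labelling grid; `round_iol_power()` rounds ties upward in power, i.e. toward a slightly more myopic outcome, the conservative choice after myopic ablation. Evaluation uses unrounded predictions by default |

Units are fixed (mm, D) and validated with actionable errors — a cohort
recorded in metres is rejected with a message suggesting a unit check, not
silently rescaled.

## The synthetic cohort generator

`generate_cohort()` emulates the two-group post-LASIK study design so that
calibration, back-calculation and evaluation are testable without patient
data. Per eye, under a single seeded stream:

1. draw AL, ACD and measured K from *truncated* normals inside the reported
   group ranges (Group 1: AL $28.08 \pm 2.50$ mm in 22.55–31.62, ACD
   $3.63 \pm 0.34$ mm in 2.83–4.30, $K_{TCRP}$ $39.24 \pm 2.38$ D /
   $K_{TRP}$ $39.13 \pm 2.49$ D in 34.45–45.96). Truncation rather than
   clipping preserves continuity and avoids boundary atoms;
   `truncnorm_moments()` gives the analytic mean/SD the cohort converges to
   (truncation shifts the AL mean down by about 0.3 mm — the tests compare
   against the analytic truncated moments, not the nominal parameters);
2. set the latent true corneal power
   $K_{true} = \beta K + \alpha + \varepsilon$, $\varepsilon \sim
   N(0, \sigma)$, with $(\beta, \alpha)$ the published calibration line and
   $\sigma$ derived at run time from the published correlation by solving
   $r = \beta \sigma_K / \sqrt{\beta^2 \sigma_K^2 + \sigma^2}$
   (`residual_sd_from_correlation()`; 1.315 D for TCRP, 1.188 D for TRP);
3. choose the implanted power from the *measured* K with
   `iol_power_for_target()` (target −0.5 D, the usual mildly myopic aim)
   and round it to the 0.5 D grid — which makes nonzero target-vs-achieved
   differences arise even noise-free;
4. simulate the achieved postoperative SE from $K_{true}$ and the implanted
   power with `predict_refraction()`, plus optional measurement noise
   (default 0).

Eyes whose simulated optics leave the validity envelope (IOL power outside
−10..40 D, |SE| > 15 D) are redrawn, with a bounded retry count; this
affects well under 1% of draws and the moment tests confirm the realised
distributions match the truncated-normal theory.

With zero residual SD and zero measurement noise the chain is exactly
invertible — `back_calculated_k()` returns $K_{true}$ to machine precision
for every eye, any seed — which is the end-to-end consistency property the
acceptance suite asserts, and a calibration on such a cohort recovers the
generating line exactly. At n = 20,000 the default presets recover the
published slopes and intercepts within three OLS standard errors (about
±0.012 on slopes and ±0.47 on intercepts); that simulation size keeps the
whole recovery run under a minute on one CPU while making the standard
errors small against the published coefficients.

### What the generator does and does not emulate

It reproduces the reported marginal distributions, the regression link
between measured and effective corneal power with the reported scatter, the
clinical IOL rounding, and the exact forward optics. It does **not**
emulate: correlation between AL, ACD and K (none is reported; they are
drawn independently — a correlation hook would be a straightforward
extension), pre-surgical history or ablation-zone effects, tomography map
structure, cataract-grade measurement noise, or hyperopic-correction eyes.
Two consequences deserve emphasis. First, because the residual SD is
derived from the published (untruncated) K SD, the realised correlation in
a truncated cohort is slightly below the published r (about 0.86 vs 0.873
for TCRP). Second, passing parameter-recovery tests shows the machinery is
self-consistent and unbiased under the stated conditions — it cannot show
that the published clinical validation numbers (e.g. 60%/90% of 30 real
eyes within ±0.5/±1.0 D) would be reproduced on real patients, since those
patient data are not deposited and per-eye prediction error is dominated by
the calibration scatter.

## Evaluation layer

Prediction error is defined as achieved minus predicted SE (positive =
hyperopic surprise). `summarize_errors()` reports mean/SD/variance of the
numeric PE, mean *and* median absolute PE (method comparisons in this
literature use either), and the percentage of eyes within ±0.5 D and
±1.0 D with *inclusive* bounds (|PE| ≤ t; the convention is rarely stated,
so it is fixed and documented here). `compare_methods()` runs the paired
battery: one-sample t per method against zero; one-way ANOVA across methods
on numeric PE plus pairwise two-sided variance-ratio F tests (the omnibus
and the pairwise reading of "ANOVA with F tests" are both emitted because
the phrasing is ambiguous in the source literature); Friedman omnibus on
absolute PE with Wilcoxon signed-rank post hocs; and McNemar tests on the
within-threshold indicators, implemented as the exact binomial test on
discordant pairs, which is well defined (p = 1) when there is no
discordance where the chi-square form is NaN. Pairwise p-values are
Bonferroni-multiplied and capped at 1; degenerate inputs (zero variance,
all-tied differences) produce explicit "not computable" notes rather than
exceptions.

## Numerical choices and limitations

* Internal computation is in metres and diopters; conversion happens at the
  argument boundary (mm in, D out).
* Vergence denominators are checked against $10^{-12}$; a singular state
  reports *which* step failed (e.g. "vergence entering the IOL").
* ELP must fall strictly inside (0, AL) for every eye processed — a hard
  error naming the constants, since it means the a-triple does not match
  the biometry.
* A back-calculated K more than 5 D from the measured K flags the record as
  suspicious (likely data-entry or pairing error) but still returns the
  value; at the calibrated residual SD this flag fires for a few eyes per
  20,000 legitimately.
* Scope limits: thin-lens optics only (no ray tracing, no thick-lens IOL
  model), scalar spherical-equivalent refraction (no toric/meridional
  power), the Haigis ELP model only, and single-map univariate Krd
  corrections (no AL- or ACD-dependent terms, no Deming/total-least-squares
  fits).
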