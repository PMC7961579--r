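---
title: "Models and methods behind osmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

osmech analyses optical-stretcher step-stress creep experiments on suspended
single cells: a dual-beam laser trap applies a contact-free surface stress of
order 1 Pa for several seconds, the cell elongates along the beam axis by a
few percent, and its shape is followed by phase-contrast imaging. The package
covers the entire analysis chain — synthetic-cohort generation, axis
tracking, viscoelastic model fitting, feature assembly, random-forest
discrimination and distributional statistics — with every stage testable
against cells whose mechanical ground truth is known. This vignette explains
the models, the tunable parameters, and the numerical and design choices.

## The mechanical model

A cell in the stretcher is treated as a Kelvin–Voigt solid: a spring
(elastic modulus $E$, Pa) in parallel with a dashpot (viscosity $\eta$,
Pa·s). Under a step stress $\sigma_0$ applied at $t = 0$, the strain creeps
as

$$\gamma(t) = \frac{\sigma_0}{E}\bigl(1 - e^{-t/\tau}\bigr), \qquad
  \tau = \eta/E ,$$

and relaxes as $\gamma(T{+}\Delta t) = \gamma(T)\,e^{-\Delta t/\tau}$ after
the laser returns to trapping power at $t = T$ (the trapping stress is
approximated as zero; a residual-stress term could be added but is off by
default because the trap "just holds" the cell).

Cells are not passive: many contract against the stretch. This is modelled
by an *activity* $a$ (Pa/s) that linearly erodes the effective stress,
$\eta\dot\gamma + E\gamma = \max(\sigma_0 - a t,\, 0)$, giving

$$\gamma(t) = \frac{\sigma_0}{E}\bigl(1-e^{-t/\tau}\bigr)
  - \frac{a}{E}\Bigl[t - \tau\bigl(1-e^{-t/\tau}\bigr)\Bigr]$$

until the clamp time $t_c = \sigma_0/a$, after which the strain decays
exponentially. The clamp expresses that a contraction cannot reverse the
sign of the optical stress in this linear model. `kv_creep()`,
`active_kv_creep()` and `kv_relax()` implement these closed forms; the test
suite checks them against an independent numerical initial-value solver to
better than $10^{-8}$ absolute over $E \in [10, 1000]$ Pa,
$\tau \in [0.1, 10]$ s, $a \in [0, 0.5]$ Pa/s.

## Deformation signals

Two dimensionless signals are derived from the tracked axes. The *relative
deformation* $d(t) = (L(t) - L_0)/L_0$ uses only the long axis ($L_0$ is
the mean long axis over the pre-stretch baseline). The *elliptic
deformation* $\varepsilon(t) = [L(t)/S(t)]/e_0 - 1$ normalises the axis
ratio by the resting ellipticity $e_0$, so it starts near zero and captures
the Poisson effect — the thinning of the short axis under elongation — that
pure elongation misses. Normalising by $e_0$ and subtracting 1 is this
package's convention; it removes the resting-shape offset so that curves of
differently shaped cells are comparable. Whether the baseline should be a
single frame or an average is a genuinely open choice; the package averages
over the pre-stretch window (default 1 s) because it halves the baseline
noise at no cost.

Two scalar derivatives matter downstream:

* **Shape restoration** $R = d(T) - d(T + 1.5\,\mathrm{s})$, the elongation
  recovered 1.5 s into relaxation, sampled at the nearest frames (no
  interpolation — mirroring a frame-based measurement). High $R$ means
  elastic, recoverable behaviour; $R \approx 0$ means dissipative.
* **Activity label**: a cell is *active* when the fitted $a$ of the active
  model (relative deformation, full window) strictly exceeds 0.001 Pa/s;
  smaller values drown in fit noise.

## Fitting

`fit_kv()` fits each model to the stretch-phase samples by bounded
trust-region Levenberg–Marquardt least squares (`minpack.lm::nls.lm`),
over the full step duration and again over its first 2 s (fast and slow
response can differ). Initialisation is $E_0 = \sigma_0/\gamma_\mathrm{end}$
and $a_0 = 0$; for $\tau$ two starts are tried — 30% of the window and the
time at which the curve first reaches 63% of its end level — and the
lower-cost fit is kept. The second, data-driven start exists because a
single fixed start can send the optimiser into a boundary local minimum
(a near-instantaneous-rise solution) even on noise-free curves. Bounds are
$E \in (0, 10^6]$ Pa, $\tau \in (10^{-3}, 10^3]$ s, $a \in [0, 10]$ Pa/s,
at most 200 iterations, cost tolerance $10^{-10}$. Flat curves and fits
escaping to the $E$ bound are flagged non-converged and carry `NA`
parameters; downstream stages treat these as explicitly masked values,
never as defaults. Eight fits are produced per cell (2 signals × 2 windows
× 2 models) and all are exported as features. The relaxation phase is not
included in the fits; it is summarised separately by the shape-restoration
statistic.

## The synthetic cohort generator

The generator exists so that every downstream stage can be tested against
known ground truth. Per class, mechanical parameters are drawn from
log-normal distributions (positivity and right skew are typical of cell
mechanics), the resting ellipticity from a normal truncated at 1, and the
activity from a zero-inflated log-normal: a cell is active with probability
0.375 (an active : non-active ratio of 0.6), and active cells have median
activity 0.08 Pa/s. The short axis co-varies with the long axis through an
effective in-plane Poisson ratio $\nu$ (short-axis strain $= -\nu\,\times$
long-axis strain), which lets relative and elliptic deformation dissociate.
Axis measurements receive i.i.d. Gaussian noise (default sd 0.05 µm);
frames where noise inverts the axis order are re-sorted so $L \ge S$ always
holds. Default frame rate is 30 Hz, with a 1 s trap-only baseline before
the step.

The documented `"clinical_like"` preset encodes a two-class study design under
the clinical three-power protocol (400/800/1200 mW assigned per cell in
random order; 10 s stretch + 2 s relaxation; stress calibration 0.38 Pa and
80 pN per 400 mW):

| parameter | PBMC-like | CTC-candidate-like |
|---|---|---|
| median $E$ (sdlog 0.45) | 30 Pa | 50 Pa |
| median $\eta$ (sdlog 0.45) | 90 Pa·s ($\tau$ = 3 s) | 40 Pa·s ($\tau$ = 0.8 s) |
| median radius (sdlog 0.18) | 4.7 µm | 7.5 µm |
| Poisson coupling $\nu$ | 0.45 | 0.2 |

The medians were calibrated analytically: $\sigma/E$ matches the
percent-level deformation scale of blood-borne cells at these stresses
($E \approx \sigma/\gamma \approx 0.8/0.028 \approx 30$ Pa); the combined
stiffness and $\nu$ contrasts make the PBMC-like end-of-stretch elliptic
deformation about twice the CTC-like median; and the $\tau$ contrast makes
the CTC-like class restore shape faster (its relaxation is nearly complete
within 1.5 s, while the dissipative PBMC-like class recovers little) —
reproducing the qualitative structure the pipeline is designed to detect,
including the larger radius of tumor-derived cells. The within-class
dispersions were then set wide enough that the two classes overlap
substantially (pooled random-forest accuracy around 0.93–0.95 rather than
1), because CTC candidates in blood are only moderately distinguishable
from PBMCs; brightness carries no class contrast (median 1.2 in both)
since nothing anchors one. The `"identical"` preset draws both class
labels from one distribution (a null cohort for calibration tests) and
`"separated"` widens the contrasts about fourfold on the log scale for
easy separability checks.

What the generator does *not* emulate: optical-force physics (the stress is
an input scalar, not a ray-optics surface profile), out-of-plane rotation,
cell clusters and debris, erythrocyte background, per-donor batch
structure, and any dependence of the stress on cell radius. Passing tests
therefore demonstrate correctness of the analysis chain under the stated
measurement model, not fidelity of any particular biological claim.

## Tracking

Rendered frames (one anti-aliased filled ellipse per frame over a noisy
background, `render_frames()`) exist to exercise the tracking stage
end-to-end. `detect_contour()` thresholds halfway between the background
median and the object peak and extracts the sub-pixel iso-intensity contour
by marching squares; among closed contours the largest enclosed area wins,
and frames without a sufficient contour are detection failures.
`fit_ellipse()` is a numerically stable direct least-squares conic fit with
the ellipse constraint; with anti-aliased rendering the half-intensity
contour coincides with the true boundary, and round-trip axis errors are
well under 2%. Isolated failed frames (runs of ≤ 2, not at the ends) are
linearly interpolated; more than 10% failures invalidates the trace. The
*degree of rotation* is defined as the cumulative absolute in-plane
orientation change over the stretch phase with 180°-wrap unwrapping — what
2-D imaging can actually measure of a rotating cell — and is invariant
under a global orientation offset.

## Features and classification

The default schema (`default_feature_schema()`, 46 features) covers the
named feature families: morphology (radius, area, relative brightness,
resting ellipticity, rotation degree), end-of-stretch relative and elliptic
deformation, shape restoration, laser power and step stress, and all
parameters of the eight fits. The random forest is evaluated by repeated
stratified k-fold cross-validation (default 5 × 10; 500 trees, Gini
impurity, $\sqrt p$ features per split, no class weighting — all
configurable). Median imputation of masked values, with added missingness
indicators, is fitted inside each training fold only. Feature importance is
*held-out permutation importance* (mean accuracy drop when one feature
column is permuted on the held-out fold), with ties broken by feature name
for determinism. A caveat applies to any single-feature permutation
importance: features that are deterministic transforms of each other split
the credit. In this schema the cell area is exactly $\pi r^2$, and under
additive axis noise the fit RMS error is itself a nearly noiseless proxy
of $1/L_0$, i.e. of size — so when size drives the classification, its
importance spreads over the radius, area and fit-error columns and no
single one of them need rank first. Interpret the size *family* jointly,
or permute grouped columns, when ranking matters. The cross-validation splits by cell; a donor-grouped split
would be the leakage-safe alternative in a multi-donor design and can be
emulated by filtering the matrix per donor before evaluation. The
progressive-input experiment re-evaluates growing feature-group prefixes on
identical fold assignments, so accuracy differences between prefixes are
paired.

## Statistics

Distributions of deformation metrics are compared with the two-sample
Kolmogorov–Smirnov test. P-values use the asymptotic null distribution
(sample sizes in scope are hundreds to thousands, where the exact method
is impractical and the asymptotic one accurate); no multiple-testing
correction is applied by default because the per-figure tests are reported
raw, with a Bonferroni option available. The KS-tested scalar per metric is
the value at the last stretch-phase frame for deformations and $R$ for
restoration. Fold enrichment is the exact ratio of proportions with an
integer-rounded headline.

One numerical subtlety: at $n_1 = n_2 = 100$ the statistic $D$ is
lattice-valued (multiples of 1/100), so the "reject at $p < 0.05$" rule has
an exact attainable size of 0.0364, not 0.05. The acceptance suite checks
calibration against this exactly computed size rather than against a noisy
Monte-Carlo estimate alone.

## Problem sizes and known limitations

The shipped tests and the acceptance script use cohorts of 200–2000 cells,
frame rates of 10–30 Hz and 96-pixel frames; these sizes make every stage's
behaviour measurable in minutes on one core while leaving the statistical
conclusions unchanged at larger n.

Two quantitative limits of the measurement model are worth stating
explicitly, because they are properties of the physics and not of the
implementation:

* **$\tau$ recovery at low stress.** At 400 mW the strain plateau of a
  soft-but-dissipative cell is ~0.013 while the per-frame strain noise is
  ~0.005 (0.05 µm on a ~10 µm axis). The median relative error of the
  fitted $\tau$ across the clinical-like cohort is then ~10–12%, at the
  Cramér–Rao bound for this signal-to-noise ratio; only more frames, larger
  cells or higher stress would reduce it.
* **Activity detection near threshold.** The sampling sd of the fitted
  activity under these conditions is 1–3 × 10⁻³ Pa/s — larger than the
  0.001 Pa/s labelling threshold. Genuinely active cells (median 0.08 Pa/s)
  are detected essentially always, but a substantial fraction of truly
  passive cells receive spurious small positive activities, so the
  active/non-active balanced accuracy saturates near 0.8 and the measured
  active : non-active ratio overstates the true 0.6. A threshold this low
  is only meaningful when the fit noise on $a$ is below ~5 × 10⁻⁴ Pa/s.

Other limitations: the Kelvin–Voigt family cannot represent power-law
rheology or multiple relaxation times; the linear activity model cannot
represent delayed or oscillatory contraction; and classification metrics on
synthetic cohorts reflect the configured class contrasts, not any clinical
performance.
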