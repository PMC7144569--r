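---
title: "Unmixing serum autofluorescence: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing serum autofluorescence: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumAF)
```

## The measurement and the model

A serum emission spectrum records fluorescence intensity against emission
wavelength at a fixed excitation wavelength (310 or 366 nm here). Several
endogenous fluorophores emit simultaneously in the 390–630 nm range —
retinol, the fluorescing free fatty acids (arachidonic, linoleic, oleic),
serum proteins via the long-wavelength tail of their emission, an
unassigned contributor near 440 nm, and, in injured animals under 366 nm
excitation, a flavin band near 560 nm. Hemolysis additionally leaves a
hemoglobin absorption dip near 410 nm that is most visible at 310 nm
excitation. The analysis problem is to attribute the measured emission
area to these components.

Every component band is a half-Gaussian modified Gaussian (GMG): the
convolution of a Gaussian (location $c$, width $\sigma_g$) with a
one-sided half-Gaussian (width $\sigma_h$),

$$
f(x) = \frac{A}{\sqrt{2\pi}\,s}
\exp\!\left(-\frac{(x-c)^2}{2s^2}\right)
\left[1 + \operatorname{erf}\!\left(
\frac{\sigma_h (x-c)}{\sigma_g \sqrt{2}\, s}\right)\right],
\qquad s = \sqrt{\sigma_g^2 + \sigma_h^2}.
$$

The amplitude $A$ is normalized to the band *area* (the erf term is odd
about $c$, so $\int f = A$ exactly); at $\sigma_h = 0$ the band is a
Gaussian of area $A$. Whether a GMG implementation normalizes amplitude
to area or to peak height is a genuine convention choice; area
normalization was chosen because it makes the quantification (areas,
percentages) read directly off the amplitude, and it is isolated in
`gmg_value()` should anyone want to change it.

Published band parameters quote the *observable* pair — peak wavelength
$\lambda$ and FWHM — not $(c, \sigma_g, \sigma_h)$. For an asymmetric
band the realized mode sits to the right of $c$ and the realized FWHM is
not $2\sqrt{2\ln 2}\,\sigma_g$, so `solve_band()` inverts
$(\lambda, \text{FWHM}, \rho)$ with $\rho = \sigma_h/\sigma_g$ into the
internal parameters. Because the GMG family is closed under affine
rescaling at fixed $\rho$, the unit band ($c = 0$, $\sigma_g = 1$) has a
mode offset $m(\rho)$ and width $w(\rho)$ that determine every other
band: $\sigma_g = \text{FWHM}/w(\rho)$,
$c = \lambda - \sigma_g m(\rho)$. The two functions are measured once on
a dense $\rho$ grid (numerical mode refinement and half-maximum
bisection on a 0.001 nm unit grid) and spline-interpolated; the
round-trip through the independent numerical descriptor extractor
`realized_shape()` reproduces $\lambda$ within 0.05 nm and FWHM within
0.1 nm across the whole component library for $\rho \in [0, 1]$ — two
orders of magnitude below instrument resolution.

The asymmetry itself is never published; the library default is
$\rho = 0.3$ (a mild red skew consistent with the reported band shapes),
fitted within $[0, 1.5]$. Because the $(\lambda, \text{FWHM})$ pair is
enforced on the *realized* band, the published values stay honored for
any $\rho$.

## The component library

`af_components(excitation, context)` returns the per-excitation registry:
the four fluorophores with their published starting $(\lambda,
\text{FWHM})$ values, the protein tail (start 400 nm, constrained below
420 nm, width free), the auxiliary 440 nm band, the negative hemoglobin
band (enabled by default at 310 nm only, opt-in at 366 nm since the
distortion it compensates is tied to 310 nm excitation), and the flavin
band (366 nm, ischemia/reperfusion context only). Starting widths for
the bands whose FWHM is not published are 80 nm (proteins), 60 nm
(undefined and flavin), 30 nm (hemoglobin), all fit-free within
[20, 150] nm. Fluorophore peaks are bounded ±10 nm around their starts
in the reference stage (preserving component identity while absorbing
solvent/matrix shifts) and fluorophore FWHMs ±15 nm, a choice in the
same identity-preserving spirit since those bounds are not published.
The registry round-trips through an editable YAML file
(`write_component_library()` / `read_component_library()`).

## Fitting protocol

Spectra are peak-normalized to 100 a.u. (`normalize_spectrum()`, which
also records the pre-normalization trapezoidal integral over the
analysis window — the "measured area" needed later) and fitted over
390–600 nm by default. The 390–600 nm window is the quantification
window of the published absolute-contribution tables; 390–630 nm (the
recorded range) is available via the `window` argument.

`fit_af_spectrum()` minimizes the squared deviation between the spectrum
and the sum of component bands with the Levenberg–Marquardt algorithm
under box bounds (`minpack.lm::nls.lm`, cost tolerance $10^{-10}$, step
tolerance $10^{-8}$, up to 6000 residual evaluations), parameterized per
component by (realized peak, realized FWHM, $\rho$, area). Two protocol
stages implement the control-first design: `reference` fits start from
library values with library bounds; `comparative` fits start from a
previously fitted reference combination with peaks bounded ±5 nm and
FWHMs ±10% around it (amplitudes fully free, $\rho$ keeps its library
bounds — the reference protocol is about locating bands, not freezing
their asymmetry). In `run_cohort_analysis()` the reference combination is
the per-parameter *median* of the converged control fits: the singular
"control combination" of the protocol has to be made precise for several
control animals, and the median is robust to a single wandering fit.

A deterministic multi-start (default 5 restarts: the plain start plus
jittered ones — peaks ±5 nm, widths ±10%, amplitudes ×[0.5, 2]
log-uniform, $\rho$ ±0.1, from the seeded generator) guards against
local minima; the best SSE wins and exact ties go to the solution
closest to its start.

### Degeneracy and the shape anchor

This is the one place where the design was genuinely open. The six
positive bands overlap heavily — at 366 nm arachidonic acid (470 nm,
93 nm FWHM) and oleic acid (462 nm, 90 nm) are nearly collinear — and
the decomposition of a single noisy spectrum is close to
non-identifiable: experiments during development showed *noiseless*
synthetic spectra fitted to SSE $\sim 10^{-14}$ whose component split
still differed from the construction by more than ten percentage points,
because flat SSE valleys let shape parameters drift and amplitudes
compensate.

Plain least squares therefore cannot resolve the split; something must
select a point on the flat manifold, and the reproducible choice is the
one closest to the published component shapes. The fit applies this as a
Tikhonov anchor appended to the residual vector: departures of each
shape parameter from the component library's value are charged
`anchor_peak` per 5 nm of peak shift and `anchor` per 10% of FWHM and
per 0.3 of $\rho$ (defaults 1 and 3). Amplitudes are never penalized —
the contribution estimates themselves remain free. The anchor targets
the *library* in both protocol stages; anchoring treated-group fits to
the fitted control combination was tried and rejected because it
propagates control-specific adaptations into the treated groups as bias.
The weights were set by studying estimator bias and variance against
synthetic ground truth: stiff widths/asymmetries with semi-free peaks
let the fit track genuine per-sample spectral shifts (which are
zero-mean across a group) while suppressing the degenerate
amplitude-trading directions. The anchor contributes negligibly to the
reported fit quality — SSE and $r^2$ are computed from the data
residuals alone — and on well-separated problems the fit agrees with an
independent grid-search + Nelder–Mead oracle to better than 0.5% in
amplitude (verified in the test suite).

Per-sample splits between the near-collinear pairs still fluctuate by
several points under measurement noise; group means are the reliable
quantity, which is how the cohort tables are meant to be read.

### Goodness of fit

`goodness_of_fit()` reports $r^2 = 1 - \text{SSE}/\text{SS}_{tot}$ over
the fitted window, the residual mean and extreme, and a Wald–Wolfowitz
runs test on residual signs (clustered signs betray an unmodeled band).
The pass bar is $r^2 \ge 0.95$ with residual mean within ±0.5 a.u.

## Quantification

`percent_contributions()` expresses each non-negative component's band
area over the analysis window as a percentage of the total *positive*
modeled area; the hemoglobin band is excluded from the denominator and
reported separately, so percentages always sum to 100 — matching the
"percentage of the overall area" convention under a fitted-components
reading. `absolute_contributions()` multiplies percentages by the
measured pre-normalization area, so percent/absolute consistency is
exact by construction and intensity rescaling leaves percentages
invariant while scaling absolutes linearly.

The AA/Ret index is computed as the ratio of group means. Computed on
the published 366 nm group-mean compositions this reproduces the
published 0.60 / 1.10 / 1.14 exactly at two decimals; the corresponding
310 nm published ratios (0.58 / 1.23 / 1.36) differ from the ratio of
the published means (0.57 / 1.24 / 1.35) in the second decimal — whether
those were computed per-sample-then-averaged or from rounded
intermediates is not stated — so the 366 nm column is the one anchored
in the acceptance tests.

`summarize_groups()` gives per-group mean ± SE (sample SD/$\sqrt{n}$)
and two-sided tests of each treatment group against the reference:
Welch's unequal-variance $t$ by default (means ± SE reporting implies a
mean comparison; the published test is unnamed), Wilcoxon rank-sum as an
option; flags follow the `*` $p \le 0.05$, `**` $p \le 0.01$ convention,
with no multiple-testing correction (none is applied in the source
tables). `reporting_filter()` drops components whose group-mean
percentage is ≤5% in every group from *rendered* tables only, mirroring
the published reporting convention.

## The synthetic cohort generator

`generate_spectrum()` / `generate_cohort()` emulate the study design so
the whole pipeline can be validated against known truth:

* **Compositions.** Per-sample component percentages are drawn from
  truncated normals around the published group means, with per-sample SD
  = published SE × $\sqrt{7}$ (the published cohort had 7 animals per
  group; 21 total), renormalized to sum to 100. Cells published only as
  "≤5%" (linoleic acid at 310 nm, proteins at 366 nm) are set to 2%
  with SD 20% of the mean; the flavin band gets 3% in I/R groups at
  366 nm; the remainder goes to the undefined 440 nm band.
* **Magnitudes.** The total integrated area is lognormal with mean equal
  to the sum of the published absolute-contribution row for that group
  and CV 0.15 — only the printed absolute magnitudes are available, and
  a 15% between-animal CV is a realistic spread for serum fluorescence
  intensities.
* **Bands.** Components are realized from the library shapes at
  $\rho = 0.3$ with uniform ±2 nm per-sample peak jitter; band *analytic*
  areas are proportional to the drawn percentages. The alternative —
  forcing in-window areas proportional to the percentages — was rejected
  because it inflates edge-truncated bands (the oleic band at 370 nm
  under 310 nm excitation) into spurious maxima at the window edge; with
  analytic-area shares the generated 310 nm sham spectra peak near
  450 nm with the 490–510 nm retinol shoulder, as real serum spectra do,
  and the in-window shares still land on the published compositions.
  The truth table therefore reports both the exact in-window share of
  each realized band (`percent` — the quantity the pipeline estimates)
  and the drawn analytic share (`percent_drawn`).
* **Distortions and noise.** At 310 nm a negative hemoglobin band
  (410 nm) is added with depth 5% of the spectrum maximum; noise is
  additive homoscedastic Gaussian with SD 0.5 a.u. on the peak-normalized
  scale (the simplest model consistent with smooth measured spectra — a
  heteroscedastic option is a one-line change in the profile). Neither
  the true serum noise magnitude nor the dip depth is quantified in the
  source; these defaults are declared, not inferred.
* **Determinism.** Per-sample seeds derive counter-style from the master
  seed (`seed + 1000·group + sample`), so any sample regenerates in
  isolation. Replicate studies should space master seeds by ≥100 000 so
  replicates share no per-sample seeds.

What the generator does *not* emulate: excitation-dependent emission
shifts of linoleic acid, solvent effects, quenching, inner-filter
effects beyond the single negative band, wavelength-dependent instrument
response, or any correlation between composition and total intensity.
Passing recovery tests on this generator therefore demonstrates that the
pipeline is a consistent estimator *under its own model class* with
realistic noise, band overlap and spectral distortions — not that every
physical confounder of real serum is handled.

## Problem sizes and numerical choices

The validation suite fits a full default cohort (3 groups × 7 samples,
366 nm, 211 points per spectrum, 5 restarts each) in a couple of minutes
on one core and checks that every fit reaches $r^2 \ge 0.95$ and that
each component's group-mean percentage is recovered within 3 absolute
points of the generator truth. The qualitative group pattern —
significantly raised fatty-acid absolute contributions after 60/60 min
ischemia/reperfusion with retinol unchanged, and raised total areas — is
checked over 100 replicate cohorts at the truth level, where it holds
with the published star pattern (the 60/120 min group, with its much
larger published SEs, has genuinely lower power at $n = 7$ and is held
to directional rather than ≥90% significance checks). Descriptor
extraction uses a 0.01 nm grid with golden-section/bisection refinement;
band areas and data integrals use trapezoidal quadrature on a 0.25 nm
grid over the analysis window, which makes the sum of component areas
equal the modeled-curve area to machine precision by linearity.

## Known limitations

* The per-sample split between strongly overlapping pairs (AA/oleic at
  366 nm) is resolved by the shape anchor, i.e. by prior information, not
  by the data; individual-sample contribution values for those pairs
  carry several points of uncertainty and should be interpreted at the
  group level.
* The protein tail is modeled as a bound-constrained GMG peaking below
  420 nm; the true protein emission peaks far below the recorded range,
  so its fitted parameters are an effective in-window description, not
  protein photophysics.
* No baseline term is fitted (the source procedure reports none);
  degenerate flat spectra are rejected rather than baseline-corrected.
* Absolute contributions inherit any instrument-to-instrument intensity
  scale; only within-study comparisons are meaningful.
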