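# serumAF

Spectral unmixing of crude-serum autofluorescence into endogenous
fluorophore components.

## The problem

Crude serum fluoresces without any added dye: retinol (vitamin A, enhanced
by binding to retinol-binding protein), some free fatty acids
(arachidonic, linoleic, oleic), serum proteins and, in injured animals,
flavins all emit in the near-UV/visible range. A single emission spectrum
recorded at 310 nm or 366 nm excitation is therefore a *mixture* of
overlapping bands, and changes in liver state (here: hepatic
ischemia/reperfusion, I/R, versus sham surgery) show up as changes in the
balance of those bands — most notably a shift of spectral weight from
retinol toward arachidonic acid.

`serumAF` implements the full analysis chain that turns raw emission
spectra into per-fluorophore contribution estimates and group-level
statistics, plus a synthetic serum-spectrum generator with known ground
truth so every stage can be validated end to end.

## The model

Each component band is a **half-Gaussian modified Gaussian (GMG)**: a
Gaussian of width σ<sub>g</sub> convolved with a one-sided half-Gaussian
of width σ<sub>h</sub>,

```
f(x) = A / (√(2π)·s) · exp(−(x−c)² / (2s²)) · [1 + erf( σ_h (x−c) / (σ_g √2 s) )],
s = √(σ_g² + σ_h²)
```

with area `A` and asymmetry ratio ρ = σ<sub>h</sub>/σ<sub>g</sub> (ρ = 0
recovers a Gaussian). Bands are specified by their *observable* peak
wavelength λ and FWHM — e.g. retinol (490 nm, 112 nm), arachidonic acid
(470 nm, 93 nm) at 366 nm excitation — and `solve_band()` inverts
(λ, FWHM, ρ) into the internal parameters exactly.

A peak-normalized spectrum (max = 100 a.u.) is fitted over the 390–600 nm
analysis window as a sum of component bands by bounded
Levenberg–Marquardt least squares (two-stage protocol: controls first
from library values, treated samples from the pooled control
combination). Each component's band area, as a percentage of the total
positive modeled area, is its **percentage contribution**; multiplying by
the pre-normalization integrated spectral area gives its **absolute
contribution**; the arachidonic-acid/retinol ratio of group means is the
headline balance index. Group means ± SE are compared against the
reference group with Welch's t (or rank-sum) tests.

## Worked example

```r
library(serumAF)

cohort <- generate_cohort(default_profiles(366), n_per_group = 3, seed = 42)
fit <- fit_af_spectrum(normalize_spectrum(cohort$spectra$sham_01))
summary(fit)
```

```
GMG spectral fit: sample 'sham_01' (group sham, excitation 366 nm, reference stage)
  window 390-600 nm, 211 points, 6 bands; converged (6 iterations)
  r-squared = 0.9998, SSE = 44.48
             name        role peak_lambda   fwhm    rho amplitude    area percent
          retinol fluorophore       490.6 112.76 0.3024   3879.48 3767.11 34.6377
 arachidonic_acid fluorophore       470.0  92.91 0.2996   2912.88 2850.03 26.2054
       oleic_acid fluorophore       462.0  90.00 0.3000    571.76  554.84  5.1016
    linoleic_acid fluorophore       428.2  72.92 0.3000   2950.65 2632.02 24.2009
         proteins        tail       400.0  80.00 0.3000     43.13   26.59  0.2445
    undefined_440   auxiliary       439.6  60.06 0.3003   1072.58 1045.15  9.6100
r-squared = 0.9998, SSE = 44.48
residual mean = 0.004389 a.u., max |residual| = 1.291 a.u.
runs test: 111 runs, z = 0.70 (p = 0.485)
PASS (requires r-squared >= 0.95 and |residual mean| <= 0.5 a.u.)
```

The fitted decomposition attributes ~35% of the modeled emission to
retinol and ~26% to arachidonic acid for this simulated sham sample, with
fit quality (r² = 0.9998) far above the 0.95 acceptance bar; the runs
test finds no structure left in the residuals.

The whole two-stage cohort analysis, with group summaries in the layout
of the published contribution tables:

```r
res <- run_cohort_analysis(cohort$spectra, restarts = 2, seed = 1)
res
```

```
Serum AF cohort analysis: 9 spectra, excitation 366 nm, window 390-600 nm
  r-squared: min 0.9997, median 0.9998

Percentage contributions (reported components):
Group summary of percent contributions (welch test vs 'sham')
     group      retinol arachidonic_acid   oleic_acid linoleic_acid  undefined_440 aa_ret
      sham 34.41 ± 3.45     25.75 ± 0.75  7.86 ± 1.59  23.20 ± 1.76    8.08 ± 0.78   0.75
  ir_60_60 25.36 ± 1.74     29.03 ± 5.31 15.67 ± 5.39  25.26 ± 1.09 0.04 ± 0.04 **   1.14
 ir_60_120 21.94 ± 8.30    35.46 ± 13.84 14.49 ± 5.97  21.74 ± 1.05 1.49 ± 0.67 **   1.62
versus reference: * p <= 0.05; ** p <= 0.01
```

The simulated I/R groups show the expected pattern: the retinol share
falls, the fatty-acid shares rise, and the AA/Ret index climbs from 0.75
(sham) past 1 after ischemia/reperfusion (at n = 3 per group the
fatty-acid shifts are not yet individually significant; the study design
uses n = 7). `write_af_results(res, "out/")` writes the manifest,
per-sample records, formatted tables and fit parameters to disk.

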