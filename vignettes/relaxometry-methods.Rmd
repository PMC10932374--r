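---
title: "Saturation-recovery relaxometry mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation-recovery relaxometry mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxmap)
```

## The measurement model

A spin-echo magnitude image depends on three material parameters — proton
density $PD$, the spin–lattice relaxation time $T_1$, and the spin–spin
relaxation time $T_2$ — and two sequence timing parameters, the repetition
time $TR$ and the echo time $TE$:

$$ IS = PD \,\bigl(1 - e^{-TR/T_1}\bigr)\, e^{-TE/T_2}. $$

Two limits motivate the two acquisition protocols. With $TE$ as short as the
scanner allows, the $T_2$ factor is close to 1 and a series of images over
increasing $TR$ encodes the $T_1$ recovery (the saturation-recovery, SR,
scheme). With $TR$ much longer than $T_1$, the recovery factor is close to 1
and a series over increasing $TE$ encodes the $T_2$ decay. The package's
default schedules are `protocol_schedule("T1")` — nine images at
$TR \in \{500, \dots, 15000\}$ ms with $TE = 3$ ms — and
`protocol_schedule("T2")` — ten images at $TE \in \{10, \dots, 200\}$ ms with
$TR = 10000$ ms. (Both $TR = 1000$ ms and $TR = 10000$ ms circulate as the
fixed repetition time of this $T_2$ protocol; the package defaults to
10000 ms, the value consistent with the long-$TR$ limit the protocol
relies on.)

Per pixel, the intensity-versus-time curve is normalized to unit maximum
(removing $PD$, which differs between pixels) and fitted by nonlinear least
squares (Levenberg–Marquardt, `minpack.lm`):

* $T_1$ recovery: $y = a - b\,e^{-c\,x/1000}$, $x = TR$ in ms, $c$ in 1/s;
* $T_2$ decay: $y = a\,e^{-c\,x/1000}$, $x = TE$ in ms.

The rate is parameterized as $c\,x/1000$ so printed coefficients are directly
comparable with the field's convention of quoting $c$ in s$^{-1}$ against
times in ms.

## The saturation-recovery readout

$T_1$ is read out as the $TR$ at which the recovery reaches
$1 - e^{-1} = 0.6321\ldots$ of its maximum, and $T_2$ as the $TE$ at which
the decay falls to $e^{-1} = 0.3679\ldots$ of its maximum. These constants
are computed in full precision, not as 4-digit literals. For the fitted
models the readouts have closed forms: `t1_readout()` implements

$$ T_1 = -\frac{1000}{c}\,\ln\frac{a - (1 - e^{-1})}{b}, $$

which reduces to $1000/c$ for the ideal normalized model $a = b = 1$, and
the $T_2$ readout is $1000/c$ exactly.

One scale subtlety matters in practice. The readout formula above assumes
the curve's *plateau* is 1, but the per-pixel normalization divides by the
observed *maximum*, which for long $T_1$ on a finite $TR$ schedule sits
below the plateau (at $T_1 = 3000$ ms the last scheduled point recovers only
$1 - e^{-5} \approx 0.993$ of it). Applying the absolute threshold to a
max-normalized curve therefore biases $T_1$ low by over 1% at the top of the
physiologic range — even on noiseless data — and, with noise, the noisy
maximum makes the bias stochastic. `fit_t1()` therefore evaluates the
readout on the plateau-normalized coefficients $(1, b/a, c)$: the 63.21%
level refers to the fitted plateau $a$, which is the proton-density
estimate. This is identical to the formula above whenever $a = b$, makes
the derived time independent of the intensity scale, and places the fitted
curve at exactly 63.21% of its plateau at the readout time (the package's
inverse-consistency test asserts this to $10^{-6}$).

Fits are judged by the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$. Non-convergence, constant input, or a
readout outside its domain yield an *invalid* result carrying
`time_ms = 0`; no exception escapes a map-level call.

A two-component model (`fit_biexponential()`) is available for voxels
mixing two water pools. Its parameterization is the natural two-term
analogue of the mono-exponential models ($a - b_1 e^{-c_1 x/1000} -
b_2 e^{-c_2 x/1000}$ for recovery, $a_1 e^{-c_1 x/1000} + a_2 e^{-c_2
x/1000}$ for decay); with at least 5 points it reports the
amplitude-dominant component in `time_ms` and both components in
`$components`, and falls back to the mono-exponential fit with a notice
when the two rates are not separable.

## Map assembly and the R² mask

`fit_map()` runs the appropriate fitter over every pixel of the selected
ROI, after optional per-frame smoothing (`none`, `mean3`, or
`gaussian:sigma`, all with reflected edges). Pixels whose fit is invalid or
whose $R^2$ falls below the threshold are masked and their time set to 0 —
the de-noising rule used for all maps, with the default threshold 0.4. The
threshold is configurable because no principled justification for the
constant exists; 0.4 is simply the operating point the reference maps used.
The mask/zero coupling (`time_ms != 0` exactly where `mask` is true) is an
exact invariant of every produced map.

On pure-noise background pixels (no proton density, Rayleigh magnitude
noise), normalization makes the fitted curve a scale-free function of nine
i.i.d. draws; the three-parameter recovery model reaches $R^2 \ge 0.4$ by
chance roughly 9% of the time, so the mask suppresses about 91% of
background pixels — not all of them. That residual is inherent to an
$R^2$ gate at 0.4 with nine samples.

ROI statistics (`roi_stats()`) report the mean and the *population* standard
deviation (divide by $n$) over kept pixels, together with $n$ so the SD's
meaning is auditable. Profiles are rasterized with Bresenham's algorithm on
pixel centers (one row of pixels), histograms count kept pixels only, and
CSV exports are lossless (17 significant digits) and byte-deterministic.
`roi_compare()` offers a Welch two-sample test between two maps' ROI pixel
populations; no multiple-testing correction is applied.

## The digital phantom and bioreactor simulator

The simulator exists so every pipeline stage is testable without scanner
time. `build_phantom()` rasterizes a test tube of demineralized water
(inner diameter 13.8 mm) holding 16 glass capillaries (outer diameter
2.3 mm, wall 0.4 mm) on a 50 mm field of view over a 512 × 512 grid —
0.09766 mm/pixel, below the 0.1 mm/pixel resolution figure the hardware
achieves. Capillaries are packed deterministically on concentric rings, so
geometry tests are exact; region membership is decided at pixel centers
(no partial-volume averaging), which keeps label counts exact at the price
of hard edges. Compartment parameters default to long-relaxation water
($T_1 = 3000$ ms, $T_2 = 1500$ ms) inside the tube and lumina, and zero
proton density in glass and air.

`bioreactor_maps()` builds a hollow-fiber bioreactor cross-section: a
medium annulus (free medium, long relaxation) inside a 10 mm tube around a
central cell region pierced by seven signal-void fibers (outer diameter
1.3 mm, one central plus a ring), on a 30 mm FOV / 128 × 128 grid. The
cell-region radius defaults to 4 mm: with the fiber geometry above, a
smaller disc leaves no interior pixels after boundary erosion, and 4 mm
matches cultures that nearly fill the extracapillary space. Cell-region
relaxation times are taken from the weekly culture table
(`mcf7_relaxation_times()`): $T_1$ falling 1100 → 673 ms and $T_2$
171 → 128 ms over six weeks, so recovery studies span the biologically
observed range.

`simulate_series()` evaluates the signal model per pixel over a schedule
and adds Rician magnitude noise — Gaussian noise of standard deviation
$\sigma$ on two quadrature channels, then the modulus — which is the
physically standard model for magnitude-reconstructed MRI; zero-signal
pixels follow a Rayleigh law with mean $\sigma\sqrt{\pi/2}$, a closed form
the tests use as an oracle. Simulation studies in the package use
$\sigma =$ (peak compartment signal)/50, i.e. SNR 50, with seeds fixed per
condition.

What the simulator deliberately does not model: $B_1$ inhomogeneity, slice
profiles, flow and diffusion, partial-volume edges, vendor reconstruction
filters, and 3D effects. Passing recovery tests on these phantoms
therefore demonstrates the correctness of the fitting and masking
machinery, not robustness to every artifact of real scanner data.

## Study sizes used by the checks

The packaged recovery studies fit 128 × 128 bioreactor frames within a
circular region covering the cell compartment (about 1100 fitted pixels
per map) for weeks 1 and 6 in both protocols, with `mean3` smoothing —
the pipeline's own pre-processing step — and ROI statistics taken over
the interior of the ground-truth cell compartment (2-pixel erosion, 108
pixels), away from fiber and medium boundaries where no homogeneous truth
exists. Recovered means land within 0.5% of the ground-truth values at
SNR 50. Unit tests use smaller grids (8–32 pixels square) chosen to keep
the full suite under a minute while still exercising every code path.

## DICOM handling

No R DICOM codec was available to build on, so the package carries a
purpose-built one: explicit-VR little-endian, one 2D frame per file,
16-bit unsigned stored pixels with RescaleSlope/Intercept applied on read,
and the tags the pipeline needs (RepetitionTime, EchoTime, PixelSpacing,
SliceThickness, SeriesInstanceUID, pixel geometry). Integer-valued frames
round-trip bit-exactly; continuous-valued frames are scaled into the
16-bit range with the scale recorded in RescaleSlope. A minimal DICOMDIR
index can be written and is used for discovery when present, with a
recursive scan as the fallback; unreadable or non-DICOM files are skipped
with a notice, never fatally. Files written by the package are verified in
the test suite against an independent standard DICOM reader. Multi-frame
enhanced objects, compressed transfer syntaxes, and DICOM networking are
out of scope. Bit depth and signedness of scanner exports vary by vendor
and are often undocumented; 16-bit unsigned is assumed.

## From contrast uptake to GAG

Glycosaminoglycans (GAGs) carry fixed negative charge, so the negatively
charged contrast agent Gd-DTPA$^{2-}$ is excluded from GAG-rich
compartments (the dGEMRIC principle). The chain implemented by
`gag_pipeline()`:

1. **Gd concentration** from each compartment's pre/post-contrast $T_1$
   (in seconds): $[\mathrm{Gd}] = (1/R)(1/T_{1,post} - 1/T_{1,pre})$, with
   relaxivity $R = 3.9$ L mmol$^{-1}$ s$^{-1}$ at 1.5 T. (The source
   prints the relaxivity unit as "mmol/L/s"; the standard relaxivity unit
   L mmol$^{-1}$ s$^{-1}$ is the dimensionally consistent reading and is
   what the implementation uses.)
2. **Fixed-charge density** from the cells/media partition by Donnan
   equilibrium with the empirical factor 2:
   $FCD = -2[\mathrm{Na}^+]\bigl(\sqrt{[\mathrm{Gd}]_c/[\mathrm{Gd}]_m} -
   \sqrt{[\mathrm{Gd}]_m/[\mathrm{Gd}]_c}\bigr)$, $[\mathrm{Na}^+] =
   154$ mM. The square-root (Donnan) form is used; FCD is positive when
   cells exclude the agent. The bracket is monotone in the ratio, so the
   relation inverts in closed form (`fcd_to_gd_ratio()`), which the tests
   use for round-trip verification at $10^{-9}$ relative error.
3. **GAG concentration**, assuming 2 moles of charge per mole of GAG
   monomer and molar mass 502.5 g/mol:
   $GAG\,[\mathrm{mg/mL}] = |FCD|/2 \times 502.5 \times 10^{-3}$. Among
   the dimensionally possible placements of the constants, this is the
   one that maps physiologic FCD values (a few mM) onto culture-scale GAG
   concentrations (1–2.5 mg/mL); e.g. $FCD = 9.11$ mM gives 2.289 mg/mL.

When neither compartment takes up contrast (pre = post on both sides) the
partition carries no information and the pipeline reports FCD = GAG = 0 by
convention rather than failing. The module operates on compartment-level
scalar $T_1$ values, not per-pixel FCD maps.

## Numerical choices and degenerate inputs

* Optimizer: `minpack.lm::nlsLM`, cost tolerance $10^{-10}$, at most 500
  iterations. Initialization: $a_0 = \max y$, $b_0 = a_0 - \min y$
  (recovery), $c_0 = 1000/\mathrm{median}(x)$; the decay fit seeds $c_0$
  from a log-linear regression where the curve is positive. All starts are
  deterministic.
* Constant or all-zero pixel curves, non-decaying decay data, and
  readout-domain violations give invalid fits (`time_ms = 0`), which the
  mask absorbs.
* Duplicate timing points in a loaded series are averaged with a notice;
  the fit expects one intensity per timing point.
* Echo time 0 is accepted in simulation and fitting as the idealized
  short-echo limit; scanner protocols always carry $TE > 0$.
* Coordinates are 0-based with pixel centers at $(i + 0.5)\cdot$spacing;
  rectangle ROIs are half-open. These conventions are fixed so profiles
  and ROI statistics are reproducible across runs and tools.

## Known limitations

The fitters implement the saturation-recovery family only — no
inversion-recovery or Look-Locker variants, no stimulated-echo correction.
The $T_2$ model carries no noise-floor offset by default (the Rician floor
biases very long-$TE$ points; an offset variant would trade bias for
variance and is not enabled). The $R^2$ gate is a pragmatic noise filter,
not a classifier; about 9% of pure-noise pixels pass it. The simulator's
hard-edged phantoms overstate how cleanly compartments separate in real
images.
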