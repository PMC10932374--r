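# relaxmap

Quantitative T1/T2 relaxation-time mapping from spin-echo DICOM series,
with a digital phantom simulator and contrast-based glycosaminoglycan
(GAG) quantification.

`relaxmap` is for people doing quantitative MRI of small samples — cell
cultures in hollow-fiber bioreactors, capillary phantoms, anything imaged
with a clinical 1.5 T scanner and exported as DICOM — who need per-pixel
relaxation times rather than qualitative contrast. It implements the
saturation-recovery (SR) workflow end to end: series discovery and
loading, per-pixel exponential fitting, goodness-of-fit masking, ROI
statistics/profiles/histograms and exports, plus the delayed
gadolinium-enhanced (dGEMRIC-style) conversion of pre-/post-contrast T1
into fixed-charge density and GAG concentration.

## The model

The spin-echo magnitude signal is

    IS = PD (1 - exp(-TR/T1)) exp(-TE/T2)

A series at varying repetition time TR (fixed short TE) encodes the T1
recovery; a series at varying echo time TE (fixed long TR) encodes the T2
decay. Per pixel, the normalized curve is fitted by nonlinear least
squares with

    T1 recovery:  y = a - b exp(-(c x)/1000)
    T2 decay:     y = a exp(-(c x)/1000)

and the relaxation time is read out at the SR fractions: T1 at the TR
where the recovery reaches 1 - e^-1 = 0.6321 of its plateau, T2 at the TE
where the decay falls to e^-1 = 0.3679 of its maximum. Pixels with
R^2 < 0.4 are masked to 0 (the de-noising rule for all maps). For GAG:

    [Gd]  = (1/R) (1/T1_post - 1/T1_pre)            R = 3.9 L/mmol/s at 1.5 T
    FCD   = -2 [Na+] (sqrt([Gd]c/[Gd]m) - sqrt([Gd]m/[Gd]c))
    GAG   = |FCD| / 2 * 502.5e-3   [mg/mL]

A digital phantom module generates ground-truth (PD, T1, T2) maps — a
16-capillary test-tube phantom and a bioreactor-like cross-section — and
simulates spin-echo series with Rician magnitude noise, writing standard
DICOM so the whole pipeline is testable without scanner time.

## Worked example

Fit the 9-point saturation-recovery reference curve (ground truth
T1 = 2250 ms):

```r
library(relaxmap)
tr    <- c(500, 700, 1000, 1500, 2000, 3000, 5000, 10000, 15000)
is_t1 <- c(0.1993, 0.2674, 0.3588, 0.4866, 0.5889,
           0.7364, 0.8916, 0.9883, 0.9987)
fit_t1(tr, is_t1)
#> <mono-T1 fit> time = 2250 ms, R^2 = 1.000000
```

Simulate a week-1 bioreactor culture, write it as DICOM, read it back,
and map T1 (cell-region ground truth 1100 ms):

```r
maps   <- bioreactor_maps(week = 1, matrix = 64)
series <- simulate_series(maps, protocol_schedule("T1"),
                          noise_sigma = 0.017, seed = 11)
dir <- file.path(tempdir(), "demo")
write_series(series, dir, dicomdir = TRUE)

catalog_series(dir)
#> <series_catalog> 9 file(s) in 1 group(s), 0 skipped
#>   2.25.20260924...: 9 frame(s), TR 500/700/1000/1500/2000/3000/5000/10000/15000 ms, TE 3 ms

map <- fit_map(load_series(catalog_series(dir)),
               roi = roi_circle(31.5, 31.5, 10), smooth = "mean3")
st  <- roi_stats(map, roi_from_mask(erode_mask(maps$labels == 2L, 1)))
sprintf("cell region T1 = %.0f +/- %.0f ms over %d pixels",
        st$mean_ms, st$sd_ms, st$n_pixels)
#> "cell region T1 = 1098 +/- 11 ms over 28 pixels"
```

The mean is the ROI average over mask-kept pixels; the spread is the
pixel (population) standard deviation. `export_map()` writes the map as
lossless CSV, a viridis PNG with colorbar, or a text report.

Convert a pre-/post-contrast T1 panel to GAG:

```r
r <- gag_pipeline(gd_panel(pre_t1_cells_ms = 1100, post_t1_cells_ms = 401,
                           pre_t1_media_ms = 3000, post_t1_media_ms = 510))
c(fcd_mM = r$fcd_mM, gag_mg_per_mL = r$gag_mg_per_mL)
#>        fcd_mM gag_mg_per_mL
#>          8.20          2.06
```

A thin command-line front end (`inst/cli/relaxmap.R`) exposes `t1map`,
`t2map`, and `gag` subcommands over the same functions.

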