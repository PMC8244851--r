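# t1phantom

Simulation and analysis of multi-site T1 relaxometry using a standardized
14-sphere NiCl₂ system phantom.

Quantitative T1 mapping promises scanner-independent tissue
characterization, but in practice the measured T1 of the *same* physical
sample differs across vendors, sites and field strengths — enough to make
clinical thresholds (e.g. separating low-grade glioma from glioblastoma by
T1) unreliable. This package provides a complete, reproducible desk-scale
laboratory for that problem: it simulates phantom acquisitions with known
ground truth, recovers the spheres by template registration, fits T1 with
the two standard protocols, and quantifies measurement bias statistically.

## Models

**Inversion recovery (IR)**, TR = 4500 ms, ten inversion times from 35 to
3000 ms. The magnitude signal follows

```
y(TI) = M0 |1 − cosθ₁₈₀·e^(−TR/T1) − (1 − cosθ₁₈₀)·e^(−TI/T1)|
        / (1 − cosθ₁₈₀·cosθ₉₀·e^(−TR/T1))
```

and is fitted by minimizing the smoothed squared-signal objective
`Σ (y² − (A + B·e^(−TI/T1))²)²` (B ≤ 0 branch), via a global grid search
refined by damped Gauss–Newton.

**Variable flip angle (VFA)**, TR = 6.6 ms, flip angles
{2, 5, 10, 20, 25, 30}°. Signals follow the Ernst equation

```
z(α) = M0 sinα (1 − E) / (1 − E cosα),   E = e^(−TR/T1)
```

fitted the same way. A transmit (B1) scale error k on the delivered angles
biases the fitted VFA T1 by ≈ k² — the central mechanism behind large
cross-vendor VFA discrepancies — while IR is nearly immune.

**Statistics.** Normalized error `100·(T1 − T1,NMR)/T1,NMR` per sphere,
group means with exact t confidence intervals, vendor × field two-way
ANOVA (Type III), per-sphere Tukey–Kramer pairwise comparisons, and
propagation of bias/dispersion onto clinical tissue T1 ranges.

## Worked example

```r
library(t1phantom)

layout <- build_layout(field_tesla = 3.0)
layout
#> <phantom_layout> 14-sphere NiCl2 T1 array at 3 T
#>   inner radius: 7.5 mm; reference T1 2033 - 23 ms

protocol <- acquisition_protocol("ir", noise_sigma = 0.01, rng_seed = 42)
series <- render_series(layout, protocol,
                        translation_mm = c(3, -2), rotation_deg = 2)

rois <- segment_series(series, layout)
rois
#> <roi_set> 14 ROIs of radius 4 mm; 52.6 pixels per ROI on average

fits <- fit_rois(roi_means(series, rois), modality = "ir",
                 tr_ms = protocol$tr_ms)
rec <- bias_records(fits, layout, vendor = "A", modality = "ir",
                    system = "A1")
rec[1:5, c("sphere", "t1_nmr_ms", "t1_measured_ms", "normalized_error_pct")]
#> # A tibble: 5 × 4
#>   sphere t1_nmr_ms t1_measured_ms normalized_error_pct
#>    <int>     <dbl>          <dbl>                <dbl>
#> 1      1      2033          2061.               1.36
#> 2      2      1489          1495.               0.378
#> 3      3      1012          1011.              -0.0545
#> 4      4       731           732.               0.163
#> 5      5       514           517.               0.606
```

The flip-angle sensitivity of VFA (the ≈ k² rule):

```r
flip_angle_sensitivity(t1_ms = 2000, tr_ms = 6.6, k_values = c(0.9, 1, 1.1))
#> # A tibble: 3 × 5
#>       k rel_angle_error t1_fit_ms rel_t1_error sensitivity
#>   <dbl>           <dbl>     <dbl>        <dbl>       <dbl>
#> 1   0.9          -0.1       1616.    -1.92e- 1        1.92
#> 2   1             0         2000.    -1.02e-15       NA
#> 3   1.1           0.100     2426.     2.13e- 1        2.13
```

A 10% under-rotation measures a 2000 ms T1 as about 1616 ms.

Multi-vendor experiments run end to end from a single config:

```r
cfg <- pipeline_config(
  vendors = tibble::tibble(vendor = c("C", "D", "E"),
                           n_systems = 4L,
                           b1_scale = c(1, 0.9, 1)),
  noise_sigma = 0.002, seed = 2024)
res <- run_pipeline(cfg)
plot_bias(res$records)       # per-sphere bias with CIs, faceted by modality
res$stats$vfa$pairwise       # Tukey-Kramer vendor comparisons per sphere
```

The miscalibrated vendor shows a ≈ −20% VFA bias at long T1 while its IR
measurements stay within a fraction of a percent — the signature that
distinguishes protocol-driven bias from random inter-system variation.

## Package layout

- `R/layout.R`, `R/simulate.R` — phantom geometry, protocols, rendering
  with Rician noise and B1 miscalibration
- `R/segmentation.R` — edge detection, rigid template registration,
  center refinement, ROI extraction
- `R/fit.R` — IR and VFA fitters (grid + Gauss–Newton), sensitivity table
- `R/stats.R` — normalized error, group summaries, ANOVA, Tukey–Kramer,
  bias propagation
- `R/io.R` — NIfTI + JSON sidecar I/O, intensity rescaling, pipeline
- `R/plot.R` — `plot_bias()` and `autoplot()` methods
- `src/kernels.cpp` — compiled grid searches, distance transform,
  registration scoring
- `vignettes/t1phantom-methods.Rmd` — full methods description and design
  rationale
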