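# areakymo

Quantification of rapid growth responses in plant hypocotyl segments from
time-lapse imaging. Auxin (and fusicoccin) trigger elongation of etiolated
hypocotyls after a lag of roughly 20 minutes, accompanied by acidification
of the apoplast — the cell-wall space — and by transcriptional reporter
activity. `areakymo` implements the full measurement chain for these
assays, for plant physiologists and image analysts who want the numbers,
not the eyeballing:

* **AreaKymo ratiometric analysis** of a dual-fluorophore apoplastic pH
  reporter (pH-insensitive reference + pH-quenched sense channel): wall
  pixels are selected on the reference channel by a strict threshold,
  per-pixel `sense/ref` ratios are packed into fixed-width rectangles
  stacked over time (a time–space "area kymograph"), and summarized as a
  boxplot series. The sense brightness follows the protonation sigmoid
  `B(pH) = 1 / (1 + 10^(pKa − pH))`, so a lower ratio means a more acidic
  wall.
* **Drift stabilization**: integer-pixel, translation-only registration by
  FFT cross-correlation on the reference channel — exact for integer
  shifts, no interpolation of ratio data.
* **Morphometry**: segment length as Feret's diameter (maximum caliper,
  pixels as unit squares), growth traces normalized so the first frame is
  exactly 100 %, line kymographs, and gravitropic tip angle
  (0° horizontal, +90° vertical).
* **Kinetics**: lag-phase estimation as the breakpoint of a continuous
  two-segment piecewise-linear least-squares fit with an exhaustive
  breakpoint search; luminescence ROI traces; auxin transit-time
  arithmetic.
* **Synthetic data with ground truth** for every modality, so each stage is
  verified by closed-loop parameter recovery.

Everything tabular goes in and out as tibbles; fitted onsets support
`tidy()`/`glance()`; every result type has an `autoplot()` method.

## Worked example

Simulate a ratiometric pH assay (acidification starting 20 min after
treatment) and run the AreaKymo pipeline end to end:

```r
library(areakymo)

out <- generate_ph_series(ph_series_config(seed = 42))
res <- run_ph_assay(out$series, assay_config(threshold = 500))

dplyr::select(res$summary, time_min, n, q1, median, q3)
#> # A tibble: 12 × 5
#>    time_min     n    q1 median    q3
#>       <dbl> <int> <dbl>  <dbl> <dbl>
#>  1        0  2160 0.699  0.716 0.732
#>  2        5  2160 0.698  0.715 0.732
#>  3       10  2160 0.698  0.714 0.732
#>  4       15  2160 0.698  0.715 0.731
#>  5       20  2160 0.698  0.715 0.732
#>  6       25  2160 0.653  0.669 0.685
#>  7       30  2160 0.608  0.623 0.639
#> # … declining toward the acidic plateau …

res$onset
#> <onset_estimate> t_break = 20 min (decrease); slopes -0.0005082 -> -0.007964 /min; SSE 0.0003993
```

The per-frame median ratio sits at ~0.715 (the noiseless value of `B(6.4)`)
through the lag phase, then falls; the changepoint fit recovers the
generator's true onset (20 min) exactly on the 5-minute sampling grid.
`autoplot(res$kymo)` renders the area kymograph, `autoplot(res$onset)` the
fitted trace.

The elongation assay works the same way — segment silhouette → Feret length
→ percentage trace → onset:

```r
el <- generate_elongation_series(growth_series_config(seed = 42))
r2 <- run_elongation_assay(el$series)
glance(r2$onset)
#> # A tibble: 1 × 8
#>   t_break_min slope_pre slope_post   sse onset_detected direction     n ...
#> 1          20   0.00996      0.501  5.78 TRUE           increase     24
```

A post-onset slope of 0.5 %/min is the generator's 30 %/hr growth rate, and
`r2$trace$length_pct[1]` is exactly 100. Finally, the back-of-the-envelope
transport check: auxin moving at 8 mm/hr entering a 1.2 mm segment from
both cut ends reaches the midpoint in

```r
transit_time(1.2, 8, bilateral = TRUE)
#> [1] 4.5
```

minutes — faster than the ~20-minute response lag, so transport is not what
sets the lag.

A thin command-line wrapper over these functions is installed at
`inst/cli/areakymo.R` (subcommands `simulate`, `ph-assay`, `elongation`,
`gravitropism`, `onset`).

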