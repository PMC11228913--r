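# crystrack

Time-resolved (4D) tomographic analysis of dissolving crystals.

`crystrack` is for experimentalists who image soluble particles dissolving
inside a perfused packed bed with time-resolved X-ray microtomography (or
any technique producing a time series of 3D gray-value volumes) and want
per-crystal dissolution kinetics out the other end. It segments soluble
crystals from an inert spacer matrix, tracks each crystal's identity
through time — including breakup into fragments — and estimates, for every
tracked crystal *n*, the individual dissolution rate

```
I_nDR(t) = -ρ · (dV/dt) / A(t)      [mg·cm⁻²·min⁻¹]
```

where ρ is the crystal density (mg·cm⁻³), V(t) the crystal volume (cm³)
and A(t) its surface area (cm²). V(t) and A(t) are smoothed by quadratic
regression and the derivative is taken analytically. For a convex crystal
whose surface recedes uniformly at speed k, the exact value is
I_nDR = ρ·k, which is how the package validates itself end-to-end on
synthetic phantoms with known ground truth.

The pipeline stages are exposed as composable functions returning tibbles:

| stage | functions |
|---|---|
| volume I/O | `read_volume_series()`, `write_volume_tiff()`, `read_run_config()` |
| segmentation | `segmentation_params()`, `crop_cylinder()`, `li_threshold()`, `segment_crystals()`, `label_components()` |
| morphometry | `measure_objects()`, `observe_series()`, `sphericity()` |
| tracking | `tracking_params()`, `link_frames()`, `match_sequences()`, `filter_pass1()`, `filter_pass2()`, `finalize_tracks()`, `track_crystals()`, `rejections()` |
| rates | `fit_quadratic()`, `indr_series()`, `compute_indr()`, `time_average_indr()` (+ `tidy()`/`glance()`/`autoplot()`) |
| population | `size_classes()`, `assign_size_class()`, `class_timecourse()`, `spatial_map()`, `track_summary()` |
| phantoms | `phantom_spec()`, `random_phantom_spec()`, `render_phantom()`, `phantom_ground_truth()`, `evaluate_tracking()` |
| everything | `analyze_dissolution()` |

## Worked example

Real data are a directory of per-timepoint TIFF volumes read with
`read_volume_series(path, voxel_size, frame_interval)`. The same pipeline
runs on a synthetic scene with known ground truth:

```r
library(crystrack)

# 8 dissolving crystals (310-390 μm) among 20 inert spacers, 128³ voxels
# at 11 μm, one frame every 6 s, top-down saturation front
spec   <- random_phantom_spec(seed = 42, n_crystals = 8, n_spacers = 20,
                              volume_shape = c(128, 128, 128),
                              equiv_diam_um = c(310, 390),
                              rate_um_min = c(40, 70))
frames <- render_phantom(spec)
res    <- analyze_dissolution(frames, estimator = "coarea")
res
#> <dissolution_analysis>
#>   64 observations in 8 frames -> 8 accepted tracks
#>   population mean I_nDR = 9.43 mg cm^-2 min^-1 (rho = 2165, coarea surfaces)
#>   per-class summary:
#> # A tibble: 1 × 4
#>   size_class tracked_crystals data_points data_points_per_crystal
#>   <fct>                 <int>       <int>                   <dbl>
#> 1 M                         8          64                       8
```

All 8 crystals are tracked through all 8 frames (64 observations, no
rejections), fall in the medium sieve class, and the population mean rate
of 9.43 mg·cm⁻²·min⁻¹ sits inside the prescribed ground-truth band
(ρ·k ranges over 9.2–15.1 mg·cm⁻²·min⁻¹ for this seed; crystals below the
saturation front dissolve for only part of the window, which lowers
lifetime averages). Per-crystal detail comes broom-style:

```r
tidy(attr(res$indr, "fits")[[1]])
#> # A tibble: 4 × 7  (first rows)
#>   track_id time_s time_min V_fit_cm3 A_fit_cm2 indr_mg_cm2_min valid
#> 1        1      0      0   0.0000263   0.00427            6.31 TRUE
#> 2        1      6      0.1 0.0000250   0.00413            6.87 TRUE
#> 3        1     12      0.2 0.0000236   0.00398            7.49 TRUE
#> 4        1     18      0.3 0.0000222   0.00382            8.18 TRUE
```

and spatially (`res$spatial`, plotted with `plot_spatial_map()`): each
crystal at its radial distance R from the cell axis and depth Z, coloured
by its lifetime-averaged rate. `plot_class_timecourse(res$timecourse)`
draws the per-class mean with the min–max envelope of individual values.

Tracks export to CSV with `write_tracks_csv()` and round-trip back with
`read_tracks_csv()`, including breakup lineage (`mother_id`).

Two surface-area estimators are available; the choice rescales absolute
rates (the default exposed-face count overestimates smooth surfaces by
1.5×, hence underestimates rates by the same factor — see the vignette),
so use `estimator = "coarea"` when absolute values matter.

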