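# keranet

Quantitative analysis of the keratin intermediate filament system in
cultured epithelial cells, for cell biologists and biophysicists studying
cytoskeletal organization, motility and mechanics — e.g. the effect of
depleting a cytolinker such as plectin on keratin network structure and
dynamics.

The package implements three analysis tracks plus the seeded synthetic
generators that make every stage testable without microscopy data:

* **Filament branch-length morphometry.** A confocal image of the keratin
  network is denoised, enhanced with the optimally oriented flux filter
  (the response is max(0, −λ_min) of the oriented-flux matrix Q(x; r),
  maximized over probe radii), thresholded, thinned to a one-voxel
  centreline, and converted to a geometric graph whose edges carry
  polyline lengths in µm. Clustered branch voxels are merged, polylines
  are low-pass filtered against raster staircase bias, and the branch
  lengths between branch points form the output distribution.
* **Keratin motility and turnover.** Time-lapse recordings are analyzed
  with normalized cross-correlation block matching (subpixel refined) to
  give vector fields and speed maps; motion-compensated intensity
  residuals give turnover maps with assembly zones (sources, positive)
  and disassembly zones (sinks, negative), with keratin mass taken
  proportional to fluorescence. Cells are optionally normalized onto a
  standard disk so maps from many cells superimpose; scalar summaries are
  the mean speed and the total bulk flow.
* **Cell mechanics.** AFM approach curves are fitted to the indentation
  power law F = A·δ^b (δ in metres, A in N/m²), free or with the exponent
  fixed at 1.8 (apparent stiffness A₁.₈), including contact-point
  detection. Magnetic-tweezers bead tracks under rectangular force pulses
  (5 s on / 10 s period, 50 frames/s) are segmented into force-normalized
  creep peaks and fitted to the power-law creep compliance
  J(t) = J₀·(t/t₀)^β, with per-group averaging (J₀ ± SEM, β ± SEM).
* **Statistics.** Group contrasts use the two-tailed
  Mann–Whitney(-Wilcoxon) test (exact for small tie-free samples); group
  summaries report mean, SD, SEM, median, min/max and 5th/95th
  percentiles.

## Worked example

```r
library(keranet)

## AFM: simulate an indentation curve at A = 111 N/m^2, b = 1.8, 10% noise,
## then fit with the exponent fixed
curve <- generate_fd_curve(fd_curve_spec(stiffness_A = 111, exponent_b = 1.8,
                                         noise_fraction = 0.10, seed = 7))
fit <- fit_power_law_fd(curve, fixed_b = 1.8)
sprintf("A_1.8 = %.1f N/m^2", fit$A)
#> "A_1.8 = 105.3 N/m^2"
sprintf("force to reach 500 nm: %.2f nN", force_at_depth(fit, 500))
#> "force to reach 500 nm: 0.48 nN"

## Magnetic tweezers: 6 pulses at the wild-type-like parameters
track <- generate_bead_track(bead_track_spec(J0 = 0.33, beta = 0.232,
                                             n_pulses = 6,
                                             noise_fraction = 0.05, seed = 7))
peaks <- extract_creep_peaks(track)
avg <- average_creep(lapply(peaks, fit_creep), peaks)
sprintf("J0 = %.3f ± %.3f µm/nN, beta = %.3f ± %.3f (n = %d peaks)",
        avg$mean_J0, avg$sem_J0, avg$mean_beta, avg$sem_beta, avg$n)
#> "J0 = 0.331 ± 0.001 µm/nN, beta = 0.229 ± 0.002 (n = 6 peaks)"

## Morphometry: branched filament phantom -> graph -> branch lengths
phantom <- generate_filament_image(filament_phantom_spec(
  field_size_px = c(240, 240), n_seeds = 2, filament_length_um = 14,
  branch_rate_per_um = 0.2, step_persistence = 0.99, noise_sd = 1, seed = 3))
res <- branch_length_pipeline(phantom$image, include_endpoint_edges = TRUE)
res$graph
#> <filament_graph> 22 nodes (3 branch, 19 endpoint), 14 edges, total 18.70 um
sprintf("mean branch length: %.2f µm (ground truth %.2f µm)",
        mean(res$lengths$length_um), mean(phantom$graph$edges$length_um))
#> "mean branch length: 1.66 µm (ground truth 1.50 µm)"

## Group comparison
mann_whitney(c(1, 2, 3), c(4, 5, 6))
#> Mann-Whitney U = 0 (n1 = 3, n2 = 3), p = 0.1 [exact]
```

The fitted A₁.₈ here is one noisy realization; averaged over 26 simulated
curves the estimator recovers the generating stiffness within a few
percent (see the test suite). `run_pipeline(keranet_config())` executes
the whole synthetic pipeline end to end and writes CSV/TIFF/JSON
artifacts with provenance metadata; a thin command-line wrapper lives at
`inst/scripts/keranet.R`.

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/keranet-methods.Rmd`) describes the models, the
estimator design choices, the synthetic generators and their limits, and
the numerical tolerances used in the tests.
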