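# fociPulse

Single-cell quantification of DNA double-strand breaks (DSBs) and
pulsatile p53 dynamics, for researchers studying the DNA damage
response in live-cell imaging data.

DSBs are counted by imaging 53BP1, which forms a microscopically
visible focus at each break; following the foci of one nucleus through
a time-lapse gives that cell's initial break number `N0` and its repair
half-life `h` under the exponential model

```
N(t) = N0 * 2^(-t / h)
```

In the same cells, a p53 reporter shows excitable pulses — all-or-none
excursions of uniform amplitude and ~5–6 h duration — and the
probability that a cell mounts a pulse rises *linearly* with its break
number, with no threshold:

```
P(pulse | N breaks) = b0 + b1 * N        (b1 ≈ 0.025 per focus:
                                          ~50% of cells at 20 breaks)
```

The package implements the complete chain as testable modules:

* **Synthetic cohorts** (`sim_config`, `simulate_cohort`,
  `render_image_stack`) — seeded generation of per-cell break counts,
  stochastic integer repair, pulsatile p53 trajectories,
  post-stimulus desensitization, DNA-content mixtures, and rendered
  multi-channel z-stacks with Poisson + read noise and full ground
  truth.
* **Foci detection** (`segment_nuclei`, `detect_foci`,
  `threshold_sweep`) — maximum projection, nucleus segmentation, white
  top-hat, Canny edges, optimal (Otsu) thresholding and
  marker-directed watershed separation of touching foci; Rcpp-backed
  image primitives.
* **Repair kinetics** (`fit_exponential`, `fit_repair`,
  `summarize_repair`) — per-cell nonlinear fits parameterized by
  half-life, with explicit flags for non-decaying or all-zero cells.
* **Pulse calling** (`normalize_trajectory`, `call_pulses`,
  `subsequent_pulse_analysis`) — baseline normalization,
  prominence-based peak detection, onset/offset/duration per pulse.
* **Dose–response statistics** (`binned_fraction`,
  `robust_linear_fit`, `rank_sum_test`, `ks_test`,
  `proportion_with_se`, `repeated_damage_analysis`,
  `classify_cell_cycle`) — binned pulse fractions (W = 4 foci), a
  robust linear probability fit with confidence band (α = 0.05),
  exact small-sample Mann–Whitney, two-sample KS, conditional response
  to repeated damage, and DAPI-based G1 vs S/G2 calls at 0.33
  normalized units.
* **Pipeline + CLI** (`pipeline_config`, `run_pipeline`, `fp_cli`) —
  end-to-end orchestration at count level (fast) or image level (full
  chain), JSON configs, CSV/JSON/TIFF I/O, deterministic given the
  seed.

## Worked example

Four hundred cells, damage averaging 20 breaks, full count-level
pipeline:

```r
library(fociPulse)
cfg <- pipeline_config(sim = sim_config(n_cells = 400,
                                        dose_mean_breaks = 20, seed = 7))
res <- run_pipeline(cfg, out_dir = "demo_out")
res$stats$fit
#> <robust_fit> p(N) = 0.1054 + 0.0183 N  (se 0.1172 / 0.0056, n = 400)
#>   Tukey bisquare (IRLS, MAD scale, c = 16); 95% confidence band over [8.0, 32.0]
subset(res$stats$bins, n > 0)[, c("bin_lo", "bin_hi", "n", "fraction")]
#>   bin_lo bin_hi   n fraction
#> 3      8     12   6     0.17
#> 4     12     16  54     0.31
#> 5     16     20 120     0.45
#> 6     20     24 131     0.53
#> 7     24     28  64     0.56
#> 8     28     32  24     0.54
```

Reading the output: the binned fractions rise roughly linearly with
break number — 53% of the 131 cells in the bin containing 20 breaks
pulsed, matching the ~50%-at-20-breaks anchor — and the robust linear
fit recovers a slope of 0.018 ± 0.006 per focus from only 400 cells
(the generative slope is 0.025; a Poisson dose concentrates cells in a
narrow break range, which widens the slope's confidence interval).
Repair fitting on the same cohort gives

```
usable repair fits: 400/400; median half-life 5.80 h; median N0 20.4
pulse-I fraction: 0.477 (generator truth 0.477)
```

against generator medians of 6 h and 20 breaks — and the detected
pulse fraction equals the ground-truth trigger fraction.

The same stages run from the shell:

```sh
Rscript inst/scripts/focipulse simulate --config cfg.json --out out/
Rscript inst/scripts/focipulse run-all  --config cfg.json --out out/ --seed 7
```

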