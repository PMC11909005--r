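# teloSPT

Single-molecule live-cell imaging of low-abundance nuclear proteins —
telomere-maintenance helicases are the motivating case — produces
two-channel movies: a sparse field of labelled protein molecules blinking
through an axial detection slice at ~134 frames/s, and a marker channel in
which shelterin-protein foci pinpoint the ~160 telomeres of a transformed
human cell. teloSPT turns such movies (or pre-linked track tables) into
the numbers that characterize the protein's nuclear dynamics, and ships a
ground-truth simulator so that every estimator in the chain can be
validated by parameter recovery.

The analysis chain:

* **Simulation** — two-state molecules (free 3D diffusion at
  `D_free` ≈ 1–2 µm²/s vs chromatin-bound at `D_bound` < 0.5 µm²/s)
  switching with exact continuous-time kinetics in a reflecting nuclear
  cylinder; a fraction `p_telo` of binding events pins at a telomere
  focus; hard axial detection slice (`dZ` = 0.7 µm), photobleaching,
  localization noise, rendered 16-bit TIFF movies with Poisson noise.
* **Tracking** — median/MAD-thresholded Gaussian spot detection with
  sub-pixel least-squares refinement, and deterministic gap-closing
  linking gated by `r_max(g) = sqrt(4 D_max (g+1) Δt)` (`D_max` = 5 µm²/s;
  0.5 µm²/s in the low-mobility mode used for residence analysis).
* **Two-state kinetics** — jump-length histograms over eight time lags
  (10 nm bins, at most four jumps per track per lag) fitted with a
  Rayleigh mixture

  `p(r|g) = w_b · r/(2 s_b²) exp(−r²/4 s_b²) + (1−w_b) · r/(2 s_f²) exp(−r²/4 s_f²)`,
  `s_x² = D_x g Δt + σ²`, `w_b = F / (F + Z_g (1−F))`,

  where the defocalization factor `Z_g` is, by default, a sampling-aware
  Monte-Carlo correction that reproduces the exact jump-counting rules
  (slice detection, two bridged gap frames, the per-track cap, bleaching);
  the classical absorbing-boundary series solution is also provided.
* **Telomere mapping** — tracks classified by the 3-pixel (0.48 µm)
  distance rule against focus centroids; per-group fits combined into the
  telomere-bound share of all bound molecules, with an occupancy-unit
  conversion and a rotation-randomization chance-colocalization
  correction.
* **Residence times** — survival curves (1 − CDF of track durations)
  fitted with exponentials and corrected for photobleaching as competing
  exponential risks, `k_off = k_obs − k_bleach`, `t½ = ln 2 / k_off`,
  with bootstrap confidence intervals.
* **Absolute abundance** — copy numbers from flow-cytometry mean
  fluorescence intensities against a reference standard, tag-loss
  correction from western-blot band intensities, and the per-telomere
  bookkeeping that follows.

## Worked example

```r
library(teloSPT)

cfg    <- simulation_config("fast", n_molecules = 8000, seed = 1)
foci   <- simulate_foci(cfg)
tracks <- simulate_tracks(cfg, foci)$tracks
tracks
#> <track_table> 16646 localizations in 2559 tracks (frame interval 0.0075 s)

fit_tracks(tracks, fit_config())
#> <two_state_fit> D_free = 1.474 um^2/s, D_bound = 0.0044 um^2/s,
#>   bound fraction = 35.2% (n = 31528 jumps, converged)
```

The generator's defaults describe S-phase-like conditions — true
`D_free` = 1.5 µm²/s and a true bound fraction of 32% — so the fit above
recovers the free diffusivity to 2% and the bound fraction to ~3
percentage points from ~31,500 pooled jumps. `run_fast_mode()` wraps the
same steps plus classification and reports the telomere-bound share;
`run_slow_mode()` performs the residence analysis:

```r
slow <- run_slow_mode(run_config(seed = 1, sim = simulation_config("slow")))
#> t1/2 telomeric: 2.30 s [2.21, 2.41], non-telomeric: 0.69 s, ratio 3.34
```

(True half-lives: 2.3 s at telomeres, 0.7 s elsewhere, under a 5 s
bleaching half-life that the analysis measures and subtracts.) Finally,
the abundance arithmetic:

```r
n <- copy_number_from_mfi(list(
  sample_plus = 400, sample_minus = 100, background_plus = 100,
  background_minus = 100, reference_plus = 10100, reference_minus = 100,
  n_reference = 1e5))
bound_molecules_per_target(n, 1/3, 0.05, 160)
#> copies: 3000; at telomeres: 50; per telomere: 0.3125
```

Three thousand copies per cell, a third of them bound, 5% of those at
telomeres: about 50 molecules — fewer than one per telomere at any
instant, which is why fast diffusive search matters for this protein
class.

A thin command-line front end over the same functions is installed at
`inst/scripts/spt-telo.R`
(`simulate | track | fit | classify | residence | abundance | run-fast | run-slow`).

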