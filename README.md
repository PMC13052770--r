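# synaptrack

Quantification of CAR T-cell **migration** and **immune-synapse dynamics**
from live-cell imaging, for labs that track T cells in tissue (e.g. brain
slices imaged every 2 minutes) and image T-cell/tumor conjugates, and want
the downstream numbers — not the microscopy — reproducible and tested.

Tracking and segmentation happen upstream (TrackMate / Fiji). `synaptrack`
takes over from there:

* **Track ingestion & QC** — TrackMate XML or tidy CSV; speed caps
  (25 µm/min default), minimum length, gap interpolation (≤2 frames) or
  splitting, edge/near-glass exclusion flags.
* **Migration statistics** — median step size and speed, confinement ratio,
  linearity of forward progression; per-track MSD with overlapping time
  intervals.
* **Random-walk classification** — fits three MSD models to the initial 40%
  of each curve and picks the winner by small-sample corrected AIC:

  | model | MSD(τ) | parameters |
  |---|---|---|
  | constrained | R²(1 − e^(−4 Dc τ / R²)) | Dc, R |
  | Brownian | 4 D τ | D (random motility coefficient) |
  | persistent (PRW) | 2 v² P² (τ/P − (1 − e^(−τ/P))) | v, P |

  with AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1), n = fitted MSD points.
  A descriptive power law A τ^α reports the diffusion exponent. Persistence
  speed v and time P are reported for PRW-classified tracks; the random
  motility coefficient (Brownian-fit D) for all tracks.
* **Population summaries** — walk-type fractions per condition, motility
  distributions, origin-aligned windrose coordinates, and a deterministic
  end-to-end pipeline (`run_motility_pipeline`).
* **Immune-synapse metrics** — calcium F/F0 normalization against the
  pre-peak baseline and area under the curve over 30 min of interaction;
  synapse area as the intersection of independently segmented T-cell and
  tumor masks; response speed (regression slope over the first minute of
  activation); MTOC docking time (first derivative peak); center-of-mass
  distance to the synapse interface.
* **Synthetic data** — seeded generators for Brownian, persistent
  (exact-update Ornstein–Uhlenbeck velocity), and confined (reflecting
  disc) tracks, imaging artifacts, calcium transients, and mask movies,
  each with analytic ground truth.

## Worked example

```r
library(synaptrack)

# 50 persistent-walk cells, 100 frames at 2 min, 0.3 um localization noise
coll <- simulate_prw(n_tracks = 50, n_frames = 100, v = 5, P = 10,
                     frame_interval = 2, localization_sigma = 0.3, seed = 7)
filtered <- apply_track_filters(coll, track_filter_config())
stats <- summarize_tracks(filtered)
head(stats[, c("track_id", "median_speed", "confinement_ratio")], 3)
#>   track_id median_speed confinement_ratio
#> 1  prw_001     4.288532         0.1671599
#> 2  prw_002     3.546502         0.3896482
#> 3  prw_003     4.044294         0.4375146

cls <- classify_tracks(filtered)
model_fractions(cls, condition = "prw_sim", step_stats = stats)
#> <population_summary> prw_sim: 50 tracks
#>   fractions: constrained 0.280 | brownian 0.000 | prw 0.720 | unclassified 0.000

mot <- do.call(rbind, lapply(cls, derive_motility))
prw <- mot[mot$best_model == "prw", ]
median(prw$persistence_speed)  # 4.56 um/min   (truth: 5)
median(prw$persistence_time)   # 17.3 min      (truth: 10)

# calcium transient: baseline 100, peak +300 at t = 5 min, tau_decay 8 min
tr <- simulate_calcium_trace(baseline = 100, peak_amplitude = 300,
                             peak_time = 5, decay_time = 8, noise_sigma = 3,
                             seed = 7)
nt <- normalize_calcium(tr)
nt$f0                  # 99.5   (truth: 100)
nt$normalized_peak     # 4.03   (truth: 1 + 300/100 = 4)
calcium_auc(nt)        # 54.2 normalized-units x min over the first 30 min
```

The numbers mean: 72% of these persistent cells are recovered as
persistent (the rest look confined over a finite window); the median
persistence speed is within ~9% of truth while persistence time, the
hardest parameter, is biased high on this 50-track sample; and the calcium
trace normalizes to its true baseline with a total flux of ~54
normalized-units·min.

## Pipeline and CLI

```r
run_motility_pipeline(list(input = "tracks.csv",
                           filter = list(min_frames = 20),
                           powerlaw = TRUE, outdir = "out"))
# -> tracks_filtered.csv, track_stats.csv, msd_curves.csv,
#    classifications.csv, windrose.csv, summary.json, run_log.txt
```

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "synaptrack.R", package = "synaptrack"))')
Rscript $CLI simulate --model prw --v 5 --p 10 --n-tracks 500 \
    --n-frames 100 --dt 2 --seed 7 --out tracks.csv
Rscript $CLI filter --in tracks.csv --out filtered.csv
Rscript $CLI classify --in filtered.csv --out classifications.csv
```

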