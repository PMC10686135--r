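# trackforest

Statistics for video-based single-cell tracking data organized as
**pedigree forests**: lineage trees rooted at the founder cells of a
time-lapse recording.

Long automated recordings of cell cultures produce, after tracking, two
tables — per-frame positions and per-cell lineage records (parent,
birth, end, terminal fate). This package *refines* ("compresses") those
tables into interpretable statistics:

* **Lineage structure** — pedigree forests, survival/extinction
  classification of trees, detection of death-free (resistant) lineages,
  and a reproducible rule for selecting a centered analysis frame
  containing a fixed number of founders.
* **Population growth** — growth curves under two normalizations,
  compressed into three coefficients by the fixed-intercept cubic
  `P3(t) = 100 + a·t + b·t² + c·t³` (so `P3(0) = 100` exactly).
* **Kinematics** — Gaussian-kernel smoothing of trajectories with
  analytic speed, arc length, and moving generalized power means
  `M_p` of speed (`M_1` vs `M_4` separates steady movers from bursty
  cells).
* **Sister-cell inheritance** — joint distributions and symmetrized
  correlations of descendant counts and subtree track lengths of
  first-generation sister subtrees; a lattice histogram smoother for
  count data and a Scott-rule kernel density estimate for continuous
  data.
* **Motion memory** — mean squared displacement from birth, sibling
  cross-displacement, and a persistent-random-walk fit
  `c(t) = 4D(t − P(1 − e^(−t/P)))` estimating the directional memory
  time `P`.
* **Cell-cell proximity** — maximal prolonged proximity events between
  concurrently tracked cells, with post-birth exclusion and per-tree
  attachment.
* **Synthetic data** — a branching-process simulator with exact
  Ornstein–Uhlenbeck persistent motion, heritable division/death/speed
  traits, resistant lineages and sister coupling, used throughout the
  tests as a statistical oracle.

The methods vignette (`vignettes/methods.Rmd`) documents the estimators,
their numerical choices and known biases — in particular why squared
displacements are fitted on unsmoothed positions for noise-free data.

## Worked example

Simulate a 48-h recording of 30 founders with heritable division times,
two death modes and a 30% resistant fraction, then run the main analyses.
Output below is the actual console output at seed 7.

```r
library(trackforest)

cfg <- sim_config(duration_h = 48, n_roots = 30, division_mean_h = 14,
                  division_trait_sd_h = 2, heritability = 0.8,
                  death_hazard_apoptotic = 0.01, death_hazard_necrotic = 0.004,
                  resistant_fraction = 0.3, noise_sd = 1)
ds <- simulate_forest(cfg, seed = 7)
ds
#> tracking_dataset: 354 cells, 34101 track points
#>   recording: 48 h at 0.1 h/frame, exposure 'synthetic', unit um
#>   roots: 30; fates: ALIVE_AT_END=167 DEATH_APOPTOTIC=18 DEATH_NECROTIC=7 DIVIDED=162

nrow(validate_dataset(ds))   # empty report = structurally valid
#> [1] 0
```

Build the forest and classify the trees:

```r
fo <- build_forest(ds)
fo
#> pedigree_forest: 30 trees, 354 cells (tree size 1-23, median 13)

cls <- classify_trees(fo)
table(cls$class); sum(cls$no_death)
#>   EXTINCT SURVIVING
#>         4        26
#> [1] 10
```

Growth curves and the cubic compression. The post-first-division curve
starts at exactly 200% — two cells of one founder — by construction:

```r
fit_growth_polynomial(population_growth_curve(fo, step = 0.5))
#> Cubic growth model  P3(t) = 100 + a t + b t^2 + c t^3
#>            a            b            c
#> -1.498930000  0.230176000 -0.000159031
#> RSS 11326.3 on 97 grid points

head(as.data.frame(population_growth_curve(fo, mode = "post_first_division",
                                           step = 0.5)), 3)
#>   time_h percent count n_trees
#> 1    0.0     200     2      26
#> 2    0.5     200     2      26
#> 3    1.0     200     2      26
```

Sister descendant-count pairs and their symmetrized correlation:

```r
dp <- sister_descendant_pairs(fo, horizon = 30, birth_window = 20)
head(as.data.frame(dp), 3)
#>   mother_id value1 value2 birth_time_h
#> 1      C001      6      6     12.41831
#> 2      C002      6      6     10.36867
#> 3      C003      2      2     17.61466

r <- pair_correlation(dp)
sprintf("pair correlation %.3f (n=%d)", r, attr(r, "n"))
#> [1] "pair correlation 0.269 (n=26)"
```

Displacement curves and the memory-time fit (on raw positions — see the
vignette for why smoothing biases squared displacements):

```r
sis <- first_generation_sisters(fo, birth_window = 20)
mc <- msd_curves(ds, c(sis$daughter1, sis$daughter2),
                 t_max = 10, step = 0.5, smoothing = FALSE)
estimate_memory_time(mc)
#> Persistent-random-walk MSD fit  c(t) = 4D (t - P (1 - exp(-t/P)))
#>   memory time P = 8.741 h, D = 157.3, RSS = 9143
```

The simulated truth is `P = 3 h`, `D = 100`: with only ~50 daughters
observed over 10 h the fit is noisy — the package's acceptance tests
calibrate the estimator on cohorts of 500 and 5,000 cells, where it
recovers `P` within 25% and 10% respectively.

Prolonged proximity events (threshold 30 µm, ≥ 4 h, 2 h post-birth
exclusion):

```r
ev <- detect_proximity_events(ds, threshold = 30)
nrow(ev); head(as.data.frame(ev), 3)
#> [1] 66
#>   cell_a cell_b t_start_h t_end_h min_dist mean_dist    relationship
#> 1   C001   C003       7.0    12.4 12.33703  20.53052 different_trees
#> 2   C003   C021      10.5    14.7 17.29616  22.06128 different_trees
#> 3  C027a  C027b      13.2    18.5  6.46820  12.23448         sisters
```

Smoothed kinematics of a single cell:

```r
st <- smooth_trajectory(ds$tracks[ds$tracks$cell_id == "C001", ])
st
#> smoothed_trajectory: 125 points on [0, 12.4] h, bandwidth 0.25 h

head(as.data.frame(moving_power_mean(speed_series(st), p = 4, window = 8)), 3)
#>   time_h      m_p
#> 1    4.0 6.303273
#> 2    4.1 6.317434
#> 3    4.2 6.324819
```

## Command line

Every analysis is scriptable through one entry point, which writes CSV/JSON
results plus a `manifest.json` recording all effective parameters, so a
rerun from the manifest reproduces the outputs byte for byte:

```sh
trackforest="$(Rscript -e 'cat(system.file("scripts", "trackforest", package = "trackforest"))')"
Rscript "$trackforest" report --tracks tracks.csv --cells cells.csv --out results --seed 1
Rscript "$trackforest" growth --config run.yaml --out results --set bandwidth=0.25
```

Commands: `simulate`, `validate`, `classify`, `growth`, `speed`,
`kinship`, `msd`, `proximity`, `report`.

## License

MIT (see `LICENSE`).
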