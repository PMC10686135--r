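---
title: "Methods: pedigree-forest statistics for single-cell tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-forest statistics for single-cell tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods implemented in
**trackforest**, the numerical choices behind them, and the design of the
synthetic-data generator used to test them. It is written for a reader who
wants to judge whether the estimators do what they claim, not as a usage
tutorial (see the README for a worked example).

## 1. Data model

A *tracking dataset* is two tables. The **track table** holds one row per
cell per frame: `cell_id`, `frame`, `time_h`, `x`, `y`. The **cell table**
holds one row per cell: `cell_id`, `parent_id` (empty for a founder),
`birth_time_h`, `end_time_h` and a terminal `fate` — one of `DIVIDED`,
`DEATH_APOPTOTIC`, `DEATH_NECROTIC`, `ALIVE_AT_END`, `LOST`. A cell's
record therefore *compresses* its track: lineage topology, lifespan and
fate are separated from the frame-by-frame positions, and most analyses
need only one of the two tables.

Two conventions matter everywhere downstream:

* **Half-open lifespans.** A cell is alive at time $t$ if
  $\mathrm{birth} \le t < \mathrm{end}$; a cell alive when the recording
  stops is also counted at the final instant (the recording boundary is
  not a biological event). Consequently a mother is *not* counted at its
  division instant while its two daughters, born at that instant, are —
  population counts jump cleanly from $n$ to $n+1$ at each division.
* **Strict validation.** `validate_dataset()` checks every structural
  invariant (two daughters per division, daughter birth equal to the
  mother's division time, tracks inside lifespans, strictly increasing
  frame times, …) and returns all violations as data; constructors and
  readers fail on the first violation with a classed condition.

## 2. Pedigree forests and growth curves

`build_forest()` groups cells into disjoint trees, one per founder.
`classify_trees()` partitions trees into `SURVIVING` (at least one member
alive at the end) and `EXTINCT`, and flags surviving trees without any
death event as `NO_DEATH` — the operational proxy for a resistant lineage.
`LOST` cells neither count as deaths nor confer survival; they simply stop
contributing information, which biases survival classification downward
for lineages with heavy tracking loss (a deliberate, conservative choice).

`select_root_frame()` reproduces the construction of a study cohort: a
rectangle centered at the midpoint of the bounding box of all first-frame
positions, with the field's aspect ratio, scaled by the smallest factor
that brings at least $n$ founders (default 100) inside. With continuous
coordinates ties have probability zero, so exactly $n$ founders are
selected; exact boundary ties are all included rather than broken
arbitrarily.

`population_growth_curve()` supports two normalizations:

* `from_start`: cells alive at each grid time as a percentage of the
  count at time zero (starts at 100).
* `post_first_division`: each tree is aligned at its first division and
  expressed as a percentage of its single founder, then the per-tree
  curves are averaged *unweighted*. Immediately after the first division
  a tree has two cells of one founder, so every per-tree curve — and any
  average of them — starts at exactly 200. This is an identity of the
  normalization, not an estimate, and the package tests it as an exact
  equality.

`fit_growth_polynomial()` compresses a from-start curve into three
numbers by least squares on
$$P_3(t) = 100 + a\,t + b\,t^2 + c\,t^3 .$$
The intercept is not a free parameter: the curve is normalized to 100 at
$t = 0$, so the fit regresses $\mathrm{percent} - 100$ on the basis
$\{t, t^2, t^3\}$ without a constant term, and $P_3(0) = 100$ holds
exactly, by construction, for every dataset. Units: $a$ in %/h, $b$ in
%/h², $c$ in %/h³.

## 3. Trajectory smoothing and kinematics

Raw tracker positions carry measurement noise of the order of a
micrometer. `smooth_trajectory()` estimates position as a
Nadaraya–Watson kernel regression over time,
$$\hat x(t) = \frac{\sum_i w_i(t)\, x_i}{\sum_i w_i(t)},\qquad
  w_i(t) = e^{-(t-t_i)^2 / 2h^2},$$
with a Gaussian kernel of standard deviation $h = 0.25$ h (15 min) by
default — about 2.5 frame intervals of the motivating 6-min recordings.
Speed is the norm of the *analytic* derivative of $\hat x$, not a finite
difference of raw points, whose magnitude would grow with the sampling
rate for noisy data. The kernel is truncated at $\pm 4h$; the neglected
weight mass is below $10^{-4}$, so smoothed positions of exactly linear
motion are reproduced to about that relative accuracy (the tests assert
this tolerance explicitly).

`track_length()` integrates smoothed speed by the trapezoid rule, and is
additive over abutting intervals. Note an edge effect inherited from the
smoother: near a track's endpoints the kernel average leans on interior
points, contracting each segment by a length of order the bandwidth.

`moving_power_mean()` computes, over centered 8-h windows, the
generalized power mean
$M_p = (\mathrm{mean}\, v^p)^{1/p}$ of the speed samples. $M_p$ is
non-decreasing in $p$ (tested as an exact inequality on random windows),
and the pair $(M_1, M_4)$ separates steadily moving cells from cells with
short speed bursts, which inflate $M_4$ much more than $M_1$. Window
centers are restricted to where the full window fits inside the track.

## 4. Sister-pair statistics

The first division of a tree defines its *first-generation sisters*. Two
pair statistics probe inheritance from the common mother:

* `sister_descendant_pairs()` — for each daughter, the number of distinct
  descendants born within a horizon (default 70 h) of the sisters' birth,
  for sisters born within an admission window (default 20 h) of the start
  of recording. Counting cells *ever born* rather than alive avoids
  conflating proliferation with death.
* `subtree_length_pairs()` — the summed smoothed track length of the
  daughter and all its descendants, each track truncated at the horizon
  (default 60 h; admission window 30 h). The truncation choice is
  exposed as a flag (`truncate = FALSE` includes whole lifespans of cells
  born before the horizon).

All pair analyses **symmetrize** first: the unordered pair
$\{v_1, v_2\}$ becomes the two points $(v_1, v_2)$ and $(v_2, v_1)$.
This makes every statistic invariant to within-pair order and forces
equal marginals, which is the natural null for sister exchangeability.
`pair_correlation()` is the Pearson correlation of the symmetrized set
(an intraclass-style correlation).

Two density estimators serve different data types:

* `smoothed_pair_histogram()` for **count-valued** pairs: a histogram on
  the integer lattice convolved with an isotropic Gaussian of standard
  deviation 1.5 lattice units. The kernel is truncated at 4 bandwidths
  and renormalized, and the grid carries a margin of the same radius, so
  the smoothed mass equals twice the number of pairs to machine-level
  accuracy (tested at $10^{-6}$ relative).
* `joint_kde()` for **continuous** pairs: a Gaussian product KDE with the
  Scott rule — kernel covariance equal to the sample covariance scaled by
  $n^{-2/(d+4)}$, $d = 2$. The grid integral is returned and tested to be
  1 within 2%.

The two are not interchangeable. Scott's rule is derived against a
unimodal (near-Gaussian) reference and *oversmooths multimodal data*: in
the package's own heritability experiment (two lineage types dividing at
9 h and 19 h, inheritance weight 0.9), the Scott KDE of descendant-count
pairs merges the two diagonal modes into one, while the lattice histogram
smoother resolves them cleanly at e.g. $(6,6)$ and $(14,14)$. The
acceptance test for multimodality therefore uses the histogram smoother —
the method designed for count data — and the KDE is validated on what it
is for: normalization and continuous, well-separated clusters.

## 5. Displacement curves and the memory time

For a cohort of cells, `msd_curves()` computes the squared displacement
from birth $c(t) = \mathbf r(t)\!\cdot\!\mathbf r(t)$, where
$\mathbf r(t)$ is the position $t$ hours after birth minus the position
at birth, and reports the cohort mean of $c(t)$ and of $c(t)/t$. Cells
that divide, die or lose coverage simply drop out of the mean (the `n`
column exposes the attrition). `sibling_cross_msd()` computes the
cross-term $c_{1,2}(t) = \mathbf r_1(t)\!\cdot\!\mathbf r_2(t)$ for
sister pairs: zero in expectation for independent walkers, positive when
sisters co-move.

For memoryless (Brownian) motion $E\,c(t) = 4Dt$, so $c(t)/t$ is flat; a
rising initial segment reveals directional persistence. The
persistent-random-walk form
$$c(t) = 4D\left(t - P\left(1 - e^{-t/P}\right)\right)$$
interpolates between ballistic ($\propto t^2$ for $t \ll P$) and
diffusive ($\propto t$ for $t \gg P$) regimes; $P$ is the *memory time*.
`estimate_memory_time()` fits it by least squares. For fixed $P$ the
amplitude $4D$ is a linear parameter, so the fit profiles it out and
optimizes over $P$ alone on $[\,\mathrm{step},\, 10\,t_{\max}]$,
comparing the interior optimum against both boundary values (golden-section
search never samples the boundary). A fit driven to the lower bound means
no resolvable persistence (Brownian limit); the upper regime means the
observation window never leaves the ballistic regime. Both are flagged as
censored rather than reported as point estimates.

### Smoothing bias of squared displacements

Kernel smoothing and squared displacements interact badly, and the
package is explicit about it. Smoothing averages positions over a time
window of width $\sim h$, which (i) shrinks the variance of the
diffusive increments inside the window and (ii) at a track's first
point — exactly the birth-anchored reference position of $c(t)$ — uses a
one-sided window, pulling the reference toward the track interior. For
Brownian motion both effects combine to a nearly *constant* contraction
of $E\,c(t)$ of order $6.4\,D h$ (the one-sided edge term $4D\bar\delta$
with $\bar\delta = h\sqrt{2/\pi}$ dominates). A constant offset in
$c(t)$ becomes a $1/t$ *slope artifact* in $c(t)/t$ — measured on
simulated noise-free Brownian cells, the regression slope of $c(t)/t$
was 8.7 with smoothing versus $-0.02$ (consistent with zero) on raw
positions.

Consequently: displacement diagnostics on noise-free synthetic data use
`smoothing = FALSE` (exact linear interpolation between frames), and the
package's Brownian-flatness and memory-time acceptance tests do so. The
default for real data remains `smoothing = TRUE`, because with
micrometer-scale measurement noise $\sigma$ the raw estimator has its own
*positive* bias $\sim 4\sigma^2$ in $c(t)$, and smoothing trades it for
the contraction above. Users fitting memory times on low-noise data
should pass `smoothing = FALSE`; either way the choice is a recorded
parameter of the run manifest.

## 6. Proximity events

`detect_proximity_events()` scans every unordered pair of
concurrently-tracked cells on the frame grid and reports *maximal*
intervals during which the center-to-center distance stays at or below a
threshold. Three guards make the events meaningful:

* a minimum duration (default 4 h) discards passing encounters;
* a post-birth exclusion (default 2 h) removes the trivial adjacency of
  freshly divided sisters;
* interruptions up to `max_gap` (default one frame) do not split an
  event, so single flickering frames are bridged.

There is no universal distance threshold — it is a configuration
parameter, with one typical cell diameter of the imaged line as the
sensible default. A bounding-box prefilter skips pairs whose tracks never
come within the threshold; it is exactly equivalent to the brute-force
scan (a track pair can only have a near frame if their bounding boxes
approach within the threshold in both coordinates), so it changes
nothing but runtime. Increasing the threshold can only extend events:
every event found at a smaller threshold is contained in an event found
at a larger one, an invariant the acceptance suite checks across 50
simulated datasets. `annotate_forest()` attaches events to pedigree
trees; a cross-tree event is attached to both trees, so per-tree cross
counts sum to exactly twice the number of cross-tree events.

## 7. The synthetic-data generator

`simulate_forest()` produces datasets with the statistical structure the
analyses assume, at desk scale. It is a branching process with motion:

* **Motion.** Per-component Ornstein–Uhlenbeck velocity with memory time
  $P$ (default 3 h) and long-time diffusion scale $D$ (default 100 µm²/h),
  discretized *exactly* at every step using the integrated-OU joint
  distribution of (velocity, displacement). The Fürth form of section 5
  therefore holds exactly in expectation at all lags — the simulator is a
  valid oracle for the memory-time estimator, not an Euler approximation
  of one. A `brownian` mode replaces the velocity process with exact
  Gaussian increments.
* **Branching.** Each cell draws competing waits: division (normal
  around a heritable lineage trait), two death modes (exponential, with
  separate hazards), and optional tracking loss; the earliest wait wins,
  and waits are clamped to at least two frame intervals so every cell is
  observable. Cells reaching the end of the recording become
  `ALIVE_AT_END`.
* **Heritability.** The division-time trait of a daughter is
  $w \cdot \mathrm{trait}_{\mathrm{mother}} + (1-w) \cdot
  \mathrm{population\ draw}$; the population draw can be a normal
  mixture, producing discrete lineage "types". A heritable log-speed
  multiplier and a per-lineage resistant flag (zero death hazards,
  inherited) complete the trait set.
* **Sister coupling.** Daughters start with correlated velocities
  ($v = \gamma v_{\mathrm{shared}} + \sqrt{1-\gamma^2}\, v_{\mathrm{own}}$,
  default $\gamma = 0.7$), giving positive sibling cross-displacement; an
  optional spring-like attraction during a post-division window prolongs
  sister proximity events.
* **Observation.** True positions are sampled at the frame grid and
  perturbed with i.i.d. Gaussian noise (default 1 µm);
  `perturb_positions()` adds further noise to an existing dataset for
  sensitivity probes.

Default scales (94 h at 6-min frames, ~200 founders in a ~1 mm field,
~20 h cycle, hazards of a few 10⁻³/h, 20% resistant lineages) emulate a
long time-lapse recording of a slowly migrating adherent line under a
cytotoxic exposure. The generator does **not** emulate: cell shape or
segmentation artifacts, crowding/contact inhibition (cells are points and
may overlap), field-edge exit (use `lost_hazard` as a proxy), non-constant
hazards, or tracker identity switches. Conclusions about those failure
modes cannot be drawn from it.

## 8. Numerical and design choices, in one place

* Kernel truncation at $\pm 4$ bandwidths everywhere (relative error
  $\sim 10^{-4}$); the pair-histogram kernel is renormalized after
  truncation so mass conservation is exact.
* The growth fit uses the normal equations via `lm.fit` on the
  $\{t, t^2, t^3\}$ basis after subtracting the fixed intercept; a
  rank check rejects degenerate grids.
* The memory-time fit is a 1-D profile optimization (`optimize`) with
  explicit boundary comparison and censoring flags, rather than a 2-D
  nonlinear fit that can silently diverge.
* Frame selection includes exact boundary ties; with continuous
  coordinates this is a probability-zero event and the target count is
  met exactly.
* Sister-pair values are stored in canonical daughter-id order and
  symmetrized at analysis time; descendant counting is cumulative
  ("ever born") — ranking subtrees by final size instead is possible via
  `count = "alive"`.
* Events and growth grids use a time tolerance of $10^{-9}$ h for
  coincidence checks; all alive-at comparisons follow the half-open
  convention of section 1.
* Analyses in the test-suite and acceptance script run on scaled-down
  problem sizes (tens of founders, 12–60 h) chosen so the whole suite
  completes in a few minutes on one CPU; the statistical claims they
  check are size-invariant (exact identities) or carry explicit
  Monte-Carlo error bounds derived from the cohort size actually used.

## 9. Limitations

* The smoother's edge bias affects every track-end-sensitive statistic
  (track length, birth-anchored displacements); section 5 describes the
  quantified case and the mitigation.
* `LOST` handling is conservative by design; datasets with heavy loss
  will under-report survival and descendant counts.
* The proximity scan is $O(\text{pairs} \times \text{frames})$ after the
  prefilter; fields with thousands of concurrently alive cells will be
  slow and would need a spatial index, which is out of scope here.
* Pair correlations assume exchangeable sisters; systematic asymmetries
  (e.g. unequal inheritance) would appear only as reduced correlation,
  not as a detected asymmetry.
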