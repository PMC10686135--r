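# Synthetic tracking datasets: a branching process with heritable lineage
# traits (division timing, death hazards, speed scale) on top of persistent
# 2D motion, observed on a regular frame grid with positional noise.
#
# The velocity process is an Ornstein-Uhlenbeck process per component,
# discretized EXACTLY at each time step (Gillespie's integrated-OU
# formulas), so the Fuerth mean-squared-displacement form
# c(t) = 4D (t - P (1 - exp(-t/P))) holds exactly in expectation.

#' Simulation configuration
#'
#' Defaults emulate the motivating recordings: 94 h at 6-min frames, a
#' couple of hundred founder cells in a ~1 mm square field (so a 100-cell
#' centered frame can be selected), binary divisions with a heritable
#' division-time trait, two competing death modes, a resistant (death-free)
#' lineage fraction, persistent-random-walk motion, and micrometer-scale
#' positional measurement noise.
#'
#' @param duration_h recording duration, hours.
#' @param frame_interval_h time between frames, hours (0.1 h = 6 min).
#' @param field_w,field_h field size, length units (default micrometers).
#' @param n_roots number of founder cells at time 0.
#' @param motion `"prw"` (persistent random walk) or `"brownian"`.
#' @param diffusion long-time diffusion scale D, length units squared per
#'   hour. 100 gives root-mean-square component speeds of a few
#'   micrometers per hour at the default persistence, typical of slowly
#'   migrating epithelial monolayer cells.
#' @param persistence_h directional memory time P of the velocity process,
#'   hours.
#' @param division_mean_h population mean of the heritable division-time
#'   trait, hours (around one cell cycle).
#' @param division_trait_sd_h population standard deviation of the trait.
#' @param division_sd_h cell-level noise of the realized division time
#'   around the lineage trait.
#' @param division_min_h hard lower bound on division times.
#' @param division_mixture_means,division_mixture_probs optional mixture of
#'   lineage types: population draws of the division-time trait come from
#'   a normal mixture with these means (sd `division_trait_sd_h`) instead
#'   of a single normal. With high heritability this yields clustered
#'   ("bimodal") lineage behavior.
#' @param heritability convex mixing weight w of trait inheritance:
#'   trait_child = w * trait_parent + (1 - w) * population draw. 0 gives
#'   i.i.d. cells, 1 perfect inheritance.
#' @param death_hazard_apoptotic,death_hazard_necrotic constant hazards of
#'   the two death modes, per hour.
#' @param resistant_fraction fraction of founder lineages with zero death
#'   hazard (inherited by all descendants).
#' @param lost_hazard hazard of losing a cell to tracking, per hour.
#' @param speed_trait_sd standard deviation of the heritable log speed
#'   multiplier (0 disables speed heterogeneity).
#' @param sister_coupling correlation of the two daughters' initial
#'   velocities: each daughter starts at
#'   gamma * v_shared + sqrt(1 - gamma^2) * v_own with v_shared drawn once
#'   per division. Produces positive sibling cross-displacement.
#' @param sister_attraction spring rate (per hour) pulling sisters toward
#'   each other during `attraction_window_h` after their birth; 0 disables.
#' @param attraction_window_h duration of the post-division attraction.
#' @param noise_sd standard deviation of additive positional measurement
#'   noise, length units.
#' @param exposure free-text label stored in the dataset metadata.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_h = 94,
                       frame_interval_h = 0.1,
                       field_w = 1000, field_h = 1000,
                       n_roots = 200,
                       motion = c("prw", "brownian"),
                       diffusion = 100,
                       persistence_h = 3,
                       division_mean_h = 20,
                       division_trait_sd_h = 2,
                       division_sd_h = 1,
                       division_min_h = 1,
                       division_mixture_means = NULL,
                       division_mixture_probs = NULL,
                       heritability = 0.5,
                       death_hazard_apoptotic = 0.004,
                       death_hazard_necrotic = 0.002,
                       resistant_fraction = 0.2,
                       lost_hazard = 0,
                       speed_trait_sd = 0,
                       sister_coupling = 0.7,
                       sister_attraction = 0,
                       attraction_window_h = 4,
                       noise_sd = 1,
                       exposure = "synthetic") {
  motion <- match.arg(motion)
  cfg <- as.list(environment())
  bad <- function(msg, ...) tf_error("tf_config_error", msg, ...)
  num_pos <- c("duration_h", "frame_interval_h", "field_w", "field_h")
  for (f in num_pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    bad("%s must be a positive number", f)
  if (cfg$frame_interval_h >= cfg$duration_h)
    bad("frame interval must be smaller than the duration")
  non_neg <- c("diffusion", "death_hazard_apoptotic", "death_hazard_necrotic",
               "lost_hazard", "speed_trait_sd", "sister_attraction",
               "noise_sd", "division_sd_h", "division_trait_sd_h")
  for (f in non_neg) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
    bad("%s must be >= 0", f)
  if (cfg$persistence_h <= 0) bad("persistence_h must be positive")
  if (cfg$n_roots < 1) bad("need at least one root cell")
  for (f in c("heritability", "resistant_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad("%s must be in [0, 1]", f)
  if (abs(cfg$sister_coupling) > 1) bad("sister_coupling must be in [-1, 1]")
  if (!is.null(cfg$division_mixture_means)) {
    if (is.null(cfg$division_mixture_probs))
      cfg$division_mixture_probs <-
        rep(1 / length(cfg$division_mixture_means),
            length(cfg$division_mixture_means))
    if (length(cfg$division_mixture_probs) !=
        length(cfg$division_mixture_means) ||
        any(cfg$division_mixture_probs < 0) ||
        abs(sum(cfg$division_mixture_probs) - 1) > 1e-9)
      bad("division_mixture_probs must be a probability vector matching the means")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d roots, %.3g h at %.3g h/frame, motion %s (D=%.3g, P=%.3g h)\n",
              x$n_roots, x$duration_h, x$frame_interval_h, x$motion,
              x$diffusion, x$persistence_h))
  cat(sprintf("  division %.3g+/-%.3g h (heritability %.2g), hazards apop %.3g necro %.3g /h, resistant %.2g\n",
              x$division_mean_h, x$division_trait_sd_h, x$heritability,
              x$death_hazard_apoptotic, x$death_hazard_necrotic,
              x$resistant_fraction))
  invisible(x)
}

# exact OU path per component on the given increment sequence.
# Returns positions at times `c(t0, t0+cumsum(dt))` and the final velocity.
ou_component <- function(n_steps, dt_vec, x0, v0, sigv2, P) {
  alpha <- exp(-dt_vec / P)
  var_v <- sigv2 * (1 - alpha^2)
  # Cov(dx, v') / Var(v') given v_prev; both from Gillespie's integrated OU
  beta <- P * (1 - alpha) / (1 + alpha)
  var_x <- 2 * sigv2 * P^2 *
    (dt_vec / P - 2 * (1 - alpha) + (1 - alpha^2) / 2)
  cov_xv <- sigv2 * P * (1 - alpha)^2
  s2 <- pmax(var_x - cov_xv^2 / pmax(var_v, 1e-300), 0)
  v <- numeric(n_steps + 1)
  v[1] <- v0
  innov <- stats::rnorm(n_steps, 0, sqrt(var_v))
  # AR(1) recursion v_j = alpha_j v_{j-1} + innov_j; only the first and
  # last steps can have a different alpha (partial frame steps), so run
  # stats::filter over each constant-alpha segment
  r <- rle(alpha)
  pos <- 1L
  for (seg in seq_along(r$lengths)) {
    idx <- pos:(pos + r$lengths[seg] - 1L)
    v[idx + 1L] <- as.numeric(stats::filter(innov[idx], r$values[seg],
                                            method = "recursive",
                                            init = v[pos]))
    pos <- pos + r$lengths[seg]
  }
  dx <- P * (1 - alpha) * v[-(n_steps + 1)] +
    beta * (v[-1] - alpha * v[-(n_steps + 1)]) +
    stats::rnorm(n_steps, 0, sqrt(s2))
  list(x = x0 + c(0, cumsum(dx)), v_end = v[n_steps + 1])
}

# times at which a cell born at `birth` and ending at `end` is simulated:
# birth, every frame time inside (birth, end), and end. Attribute `frame`
# marks which entries are observation frames.
path_times <- function(birth, end, dt) {
  k0 <- ceiling(birth / dt - 1e-6)
  k1 <- floor(end / dt + 1e-6)
  frames <- if (k1 >= k0) (k0:k1) else integer(0)
  tt <- frames * dt
  fr <- frames
  if (length(tt) == 0L || tt[1] > birth + TF_TIME_TOL) {
    tt <- c(birth, tt)
    fr <- c(NA_integer_, fr)
  }
  n <- length(tt)
  if (tt[n] < end - TF_TIME_TOL) {
    tt <- c(tt, end)
    fr <- c(fr, NA_integer_)
  }
  list(t = tt, frame = fr)
}

# simulate the true path of one cell; returns positions at path_times
sim_path <- function(cfg, birth, end, x0, y0, v0, d_cell) {
  pt <- path_times(birth, end, cfg$frame_interval_h)
  tt <- pt$t
  n <- length(tt) - 1L
  if (n == 0L)
    return(list(t = tt, frame = pt$frame, x = x0, y = y0,
                x_end = x0, y_end = y0, v_end = v0))
  dtv <- diff(tt)
  if (cfg$motion == "brownian") {
    x <- x0 + c(0, cumsum(stats::rnorm(n, 0, sqrt(2 * d_cell * dtv))))
    y <- y0 + c(0, cumsum(stats::rnorm(n, 0, sqrt(2 * d_cell * dtv))))
    ve <- c(0, 0)
  } else {
    sigv2 <- d_cell / cfg$persistence_h
    cx <- ou_component(n, dtv, x0, v0[1], sigv2, cfg$persistence_h)
    cy <- ou_component(n, dtv, y0, v0[2], sigv2, cfg$persistence_h)
    x <- cx$x; y <- cy$x
    ve <- c(cx$v_end, cy$v_end)
  }
  list(t = tt, frame = pt$frame, x = x, y = y,
       x_end = x[n + 1], y_end = y[n + 1], v_end = ve)
}

# population draw of the division-time trait
draw_trait <- function(cfg, n = 1) {
  if (!is.null(cfg$division_mixture_means)) {
    comp <- sample.int(length(cfg$division_mixture_means), n, replace = TRUE,
                       prob = cfg$division_mixture_probs)
    stats::rnorm(n, cfg$division_mixture_means[comp], cfg$division_trait_sd_h)
  } else {
    stats::rnorm(n, cfg$division_mean_h, cfg$division_trait_sd_h)
  }
}

# decide fate and end time for a cell born at `birth`
decide_fate <- function(cfg, birth, trait, resistant) {
  min_life <- 2 * cfg$frame_interval_h
  draw_exp <- function(h) if (h <= 0) Inf else stats::rexp(1, h)
  w_div <- max(stats::rnorm(1, trait, cfg$division_sd_h), cfg$division_min_h)
  w_apo <- if (resistant) Inf else draw_exp(cfg$death_hazard_apoptotic)
  w_nec <- if (resistant) Inf else draw_exp(cfg$death_hazard_necrotic)
  w_lost <- draw_exp(cfg$lost_hazard)
  waits <- pmax(c(div = w_div, apo = w_apo, nec = w_nec, lost = w_lost),
                min_life)
  k <- which.min(waits)
  end <- birth + waits[k]
  if (end >= cfg$duration_h - TF_TIME_TOL)
    list(fate = "ALIVE_AT_END", end = cfg$duration_h)
  else
    list(fate = c("DIVIDED", "DEATH_APOPTOTIC", "DEATH_NECROTIC",
                  "LOST")[k], end = unname(end))
}

#' Simulate a synthetic tracking dataset
#'
#' Runs the branching-process trajectory simulator defined by a
#' [sim_config()] and returns a validated [tracking_dataset()]. The result
#' is reproducible: the same `(cfg, seed)` yields an identical dataset.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for all randomness.
#' @return A `tracking_dataset` that passes [validate_dataset()].
#' @export
simulate_forest <- function(cfg, seed = 1) {
  if (!inherits(cfg, "sim_config"))
    tf_error("tf_config_error", "cfg must be a sim_config object")
  set.seed(seed)
  dt <- cfg$frame_interval_h
  sigv2 <- cfg$diffusion / cfg$persistence_h
  stationary_v <- function() stats::rnorm(2, 0, sqrt(sigv2))

  recs <- list()
  trs <- list()
  # realize one cell completely; returns daughter specs (possibly empty)
  realize <- function(spec, coupled_path = NULL) {
    fate <- decide_fate(cfg, spec$birth, spec$trait, spec$resistant)
    d_cell <- cfg$diffusion * spec$speed_mult^2
    path <- if (is.null(coupled_path)) {
      sim_path(cfg, spec$birth, fate$end, spec$x, spec$y, spec$v, d_cell)
    } else coupled_path
    obs <- !is.na(path$frame)
    if (any(obs))
      trs[[length(trs) + 1L]] <<- data.frame(
        cell_id = spec$id, frame = path$frame[obs],
        time_h = path$t[obs],
        x = path$x[obs] + stats::rnorm(sum(obs), 0, cfg$noise_sd),
        y = path$y[obs] + stats::rnorm(sum(obs), 0, cfg$noise_sd),
        stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <<- data.frame(
      cell_id = spec$id, parent_id = spec$parent,
      birth_time_h = spec$birth, end_time_h = fate$end, fate = fate$fate,
      stringsAsFactors = FALSE)
    if (fate$fate != "DIVIDED") return(list())
    v_shared <- stationary_v()
    g <- cfg$sister_coupling
    mk <- function(tag) {
      list(id = paste0(spec$id, tag), parent = spec$id, birth = fate$end,
           x = path$x_end, y = path$y_end,
           v = g * v_shared + sqrt(max(0, 1 - g^2)) * stationary_v(),
           trait = cfg$heritability * spec$trait +
             (1 - cfg$heritability) * draw_trait(cfg),
           resistant = spec$resistant,
           speed_mult = exp(cfg$heritability * log(spec$speed_mult) +
                              (1 - cfg$heritability) *
                                stats::rnorm(1, 0, cfg$speed_trait_sd)))
    }
    list(mk("a"), mk("b"))
  }

  # jointly realize a sister pair with post-division mutual attraction:
  # independent OU increments, re-integrated with a spring term on the
  # common frame schedule inside the attraction window
  realize_pair <- function(s1, s2) {
    f1 <- decide_fate(cfg, s1$birth, s1$trait, s1$resistant)
    f2 <- decide_fate(cfg, s2$birth, s2$trait, s2$resistant)
    p1 <- sim_path(cfg, s1$birth, f1$end, s1$x, s1$y, s1$v,
                   cfg$diffusion * s1$speed_mult^2)
    p2 <- sim_path(cfg, s2$birth, f2$end, s2$x, s2$y, s2$v,
                   cfg$diffusion * s2$speed_mult^2)
    k_attr <- cfg$sister_attraction
    t_stop <- s1$birth + cfg$attraction_window_h
    n_common <- min(length(p1$t), length(p2$t))
    # re-integrate positions with the coupling drift
    x1 <- p1$x; y1 <- p1$y; x2 <- p2$x; y2 <- p2$y
    for (j in 2:n_common) {
      if (p1$t[j] > t_stop + TF_TIME_TOL) break
      h <- p1$t[j] - p1$t[j - 1]
      pull_x <- k_attr * (x2[j - 1] - x1[j - 1]) * h
      pull_y <- k_attr * (y2[j - 1] - y1[j - 1]) * h
      x1[j:length(x1)] <- x1[j:length(x1)] + pull_x
      y1[j:length(y1)] <- y1[j:length(y1)] + pull_y
      x2[j:length(x2)] <- x2[j:length(x2)] - pull_x
      y2[j:length(y2)] <- y2[j:length(y2)] - pull_y
    }
    p1$x <- x1; p1$y <- y1; p1$x_end <- x1[length(x1)]; p1$y_end <- y1[length(y1)]
    p2$x <- x2; p2$y <- y2; p2$x_end <- x2[length(x2)]; p2$y_end <- y2[length(y2)]
    # replay through realize() with the fates re-decided: not allowed —
    # fates were consumed above, so inline the bookkeeping instead
    emit <- function(spec, fate, path) {
      obs <- !is.na(path$frame)
      if (any(obs))
        trs[[length(trs) + 1L]] <<- data.frame(
          cell_id = spec$id, frame = path$frame[obs], time_h = path$t[obs],
          x = path$x[obs] + stats::rnorm(sum(obs), 0, cfg$noise_sd),
          y = path$y[obs] + stats::rnorm(sum(obs), 0, cfg$noise_sd),
          stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <<- data.frame(
        cell_id = spec$id, parent_id = spec$parent,
        birth_time_h = spec$birth, end_time_h = fate$end, fate = fate$fate,
        stringsAsFactors = FALSE)
      if (fate$fate != "DIVIDED") return(list())
      v_shared <- stationary_v()
      g <- cfg$sister_coupling
      lapply(c("a", "b"), function(tag) {
        list(id = paste0(spec$id, tag), parent = spec$id, birth = fate$end,
             x = path$x_end, y = path$y_end,
             v = g * v_shared + sqrt(max(0, 1 - g^2)) * stationary_v(),
             trait = cfg$heritability * spec$trait +
               (1 - cfg$heritability) * draw_trait(cfg),
             resistant = spec$resistant,
             speed_mult = exp(cfg$heritability * log(spec$speed_mult) +
                                (1 - cfg$heritability) *
                                  stats::rnorm(1, 0, cfg$speed_trait_sd)))
      })
    }
    c(emit(s1, f1, p1), emit(s2, f2, p2))
  }

  roots <- lapply(seq_len(cfg$n_roots), function(i) {
    list(id = sprintf("C%03d", i), parent = NA_character_, birth = 0,
         x = stats::runif(1, 0, cfg$field_w),
         y = stats::runif(1, 0, cfg$field_h),
         v = stationary_v(),
         trait = draw_trait(cfg),
         resistant = stats::runif(1) < cfg$resistant_fraction,
         speed_mult = exp(stats::rnorm(1, 0, cfg$speed_trait_sd)))
  })
  queue <- roots
  while (length(queue) > 0) {
    spec <- queue[[1]]
    queue <- queue[-1]
    if (is.list(spec) && !is.null(spec$pair)) {
      queue <- c(queue, realize_pair(spec$pair[[1]], spec$pair[[2]]))
    } else {
      kids <- realize(spec)
      if (length(kids) == 2 && cfg$sister_attraction > 0) {
        queue <- c(queue, list(list(pair = kids)))
      } else {
        queue <- c(queue, kids)
      }
    }
  }
  tracks <- do.call(rbind, trs)
  cells <- do.call(rbind, recs)
  o <- order(cells$cell_id)
  cells <- cells[o, , drop = FALSE]
  tracks <- tracks[order(tracks$cell_id, tracks$frame), , drop = FALSE]
  tracking_dataset(tracks, cells,
                   frame_interval_h = cfg$frame_interval_h,
                   duration_h = cfg$duration_h,
                   exposure = cfg$exposure,
                   spatial_unit = "um")
}

#' Perturb the positions of a tracking dataset
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sd` to every observed
#' coordinate. Lineage records and topology are untouched, so re-running
#' an analysis on the perturbed dataset probes its sensitivity to
#' positional measurement error. `sd = 0` returns the dataset unchanged.
#'
#' @param ds a [tracking_dataset()].
#' @param sd noise standard deviation in the dataset's length unit.
#' @param seed integer seed.
#' @return A `tracking_dataset` with perturbed coordinates.
#' @export
perturb_positions <- function(ds, sd, seed = 1) {
  if (!is.numeric(sd) || sd < 0)
    tf_error("tf_input_error", "noise sd must be >= 0")
  if (sd == 0) return(ds)
  set.seed(seed)
  n <- nrow(ds$tracks)
  ds$tracks$x <- ds$tracks$x + stats::rnorm(n, 0, sd)
  ds$tracks$y <- ds$tracks$y + stats::rnorm(n, 0, sd)
  ds
}
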