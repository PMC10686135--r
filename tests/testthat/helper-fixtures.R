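# Shared fixtures: hand-built miniature datasets and scaled-down
# simulation configurations. Everything is generated in code.

# a dataset with straight-line tracks for the given cell specs
# specs: data.frame(cell_id, parent_id, birth, end, fate, x0, y0, vx, vy)
make_linear_dataset <- function(specs, dt = 0.1, duration = max(specs$end),
                                check = TRUE) {
  trs <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    k <- seq(ceiling(s$birth / dt - 1e-9), floor(s$end / dt + 1e-9))
    tt <- k * dt
    data.frame(cell_id = s$cell_id, frame = as.integer(k), time_h = tt,
               x = s$x0 + s$vx * (tt - s$birth),
               y = s$y0 + s$vy * (tt - s$birth),
               stringsAsFactors = FALSE)
  })
  cells <- data.frame(cell_id = specs$cell_id, parent_id = specs$parent_id,
                      birth_time_h = specs$birth, end_time_h = specs$end,
                      fate = specs$fate, stringsAsFactors = FALSE)
  tracking_dataset(do.call(rbind, trs), cells, frame_interval_h = dt,
                   duration_h = duration, check = check)
}

# one root alive for `dur` hours, moving at (vx, vy) from (x0, y0)
single_cell_dataset <- function(dur = 10, vx = 0, vy = 0, x0 = 50, y0 = 50,
                                dt = 0.1) {
  make_linear_dataset(data.frame(
    cell_id = "A", parent_id = NA_character_, birth = 0, end = dur,
    fate = "ALIVE_AT_END", x0 = x0, y0 = y0, vx = vx, vy = vy), dt = dt,
    duration = dur)
}

# a root dividing once at t_div; daughters d1/d2 with given fates
division_dataset <- function(t_div = 10, dur = 20,
                             fates = c("ALIVE_AT_END", "ALIVE_AT_END"),
                             ends = c(dur, dur), v = c(1, -1)) {
  make_linear_dataset(data.frame(
    cell_id = c("A", "Aa", "Ab"),
    parent_id = c(NA, "A", "A"),
    birth = c(0, t_div, t_div),
    end = c(t_div, ends[1], ends[2]),
    fate = c("DIVIDED", fates[1], fates[2]),
    x0 = c(50, 50, 50), y0 = c(50, 50, 50),
    vx = c(0, v[1], v[2]), vy = 0), duration = dur)
}

# small, fast simulation config for property tests
quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(duration_h = 24, n_roots = 20, division_mean_h = 10,
         division_trait_sd_h = 1, death_hazard_apoptotic = 0.004,
         death_hazard_necrotic = 0.002, resistant_fraction = 0.25,
         noise_sd = 0.5),
    list(...))
  do.call(sim_config, args)
}

# deterministic synchronous division every T hours, no death, no noise
deterministic_cfg <- function(T = 8, duration = 24, n_roots = 4) {
  sim_config(duration_h = duration, n_roots = n_roots,
             division_mean_h = T, division_trait_sd_h = 0,
             division_sd_h = 0, heritability = 1,
             death_hazard_apoptotic = 0, death_hazard_necrotic = 0,
             resistant_fraction = 0, noise_sd = 0)
}
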