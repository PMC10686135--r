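# Synthetic dataset generator: reproducibility, structural invariants,
# motion statistics, heritable traits.

test_that("invalid configurations are rejected with classed errors", {
  expect_error(sim_config(duration_h = -1), class = "tf_config_error")
  expect_error(sim_config(heritability = 1.5), class = "tf_config_error")
  expect_error(sim_config(sister_coupling = 2), class = "tf_config_error")
  expect_error(sim_config(division_mixture_means = c(10, 20),
                          division_mixture_probs = c(0.5, 0.6)),
               class = "tf_config_error")
  expect_error(simulate_forest(list()), class = "tf_config_error")
})

test_that("the same configuration and seed reproduce the dataset exactly", {
  cfg <- quick_cfg()
  a <- simulate_forest(cfg, seed = 123)
  b <- simulate_forest(cfg, seed = 123)
  expect_identical(a$cells, b$cells)
  expect_identical(a$tracks, b$tracks)
  c <- simulate_forest(cfg, seed = 124)
  expect_false(identical(a$tracks$x, c$tracks$x))
})

test_that("simulated lineage records satisfy the structural invariants", {
  ds <- simulate_forest(quick_cfg(), seed = 55)
  cl <- ds$cells
  expect_equal(nrow(validate_dataset(ds)), 0)
  expect_equal(sum(is.na(cl$parent_id)), 20)
  # every divided cell has exactly two daughters born at its end time
  for (id in cl$cell_id[cl$fate == "DIVIDED"]) {
    d <- cl[!is.na(cl$parent_id) & cl$parent_id == id, ]
    expect_equal(nrow(d), 2)
    expect_equal(d$birth_time_h,
                 rep(cl$end_time_h[cl$cell_id == id], 2), tolerance = 1e-9)
  }
  # every lifespan covers at least two frames
  expect_true(all(cl$end_time_h - cl$birth_time_h >= 2 * 0.1 - 1e-9))
  # terminal cells end at the recording end iff alive at end
  expect_true(all((cl$fate == "ALIVE_AT_END") == (cl$end_time_h >= 24 - 1e-9)))
})

test_that("a deterministic configuration doubles on schedule", {
  ds <- simulate_forest(deterministic_cfg(T = 8, duration = 24, n_roots = 3),
                        seed = 9)
  cl <- ds$cells
  # generations: 3 roots, 6, 12 -> 21 cells
  expect_equal(nrow(cl), 21)
  expect_setequal(round(unique(cl$birth_time_h), 6), c(0, 8, 16))
  expect_equal(sum(cl$fate == "ALIVE_AT_END"), 12)
})

test_that("brownian displacement grows linearly in time", {
  cfg <- sim_config(duration_h = 8, n_roots = 250, motion = "brownian",
                    diffusion = 100, division_mean_h = 1000,
                    death_hazard_apoptotic = 0, death_hazard_necrotic = 0,
                    resistant_fraction = 0, noise_sd = 0, field_w = 5000,
                    field_h = 5000)
  ds <- simulate_forest(cfg, seed = 33)
  mc <- msd_curves(ds, ds$cells$cell_id, t_max = 6, step = 0.5,
                   smoothing = FALSE)
  # mean c(t) should track 4 D t; per-point relative error shrinks as
  # 1/sqrt(n), allow 3 standard errors (relative SE of a chi^2 mean ~
  # sqrt(2/n) per axis pair)
  rel_tol <- 3 * sqrt(2 / 250)
  expect_true(all(abs(mc$curve$mean_c / (4 * 100 * mc$curve$t_h) - 1) <
                    rel_tol))
})

test_that("persistent motion follows the Fuerth curve in expectation", {
  cfg <- sim_config(duration_h = 16, n_roots = 400, motion = "prw",
                    diffusion = 100, persistence_h = 3,
                    division_mean_h = 1000, death_hazard_apoptotic = 0,
                    death_hazard_necrotic = 0, resistant_fraction = 0,
                    noise_sd = 0, field_w = 5000, field_h = 5000)
  ds <- simulate_forest(cfg, seed = 44)
  mc <- msd_curves(ds, ds$cells$cell_id, t_max = 12, step = 0.5,
                   smoothing = FALSE)
  theory <- 4 * 100 * (mc$curve$t_h - 3 * (1 - exp(-mc$curve$t_h / 3)))
  rel_tol <- 4 * sqrt(2 / 400)
  expect_true(all(abs(mc$curve$mean_c / theory - 1) < rel_tol))
})

test_that("perfect heritability preserves the division trait in a lineage", {
  cfg <- sim_config(duration_h = 40, n_roots = 10, division_mean_h = 10,
                    division_trait_sd_h = 3, division_sd_h = 0,
                    heritability = 1, death_hazard_apoptotic = 0,
                    death_hazard_necrotic = 0, resistant_fraction = 0,
                    noise_sd = 0)
  ds <- simulate_forest(cfg, seed = 66)
  cl <- ds$cells
  fo <- build_forest(ds)
  for (r in names(fo$trees)) {
    m <- cl[cl$cell_id %in% fo$trees[[r]] & cl$fate == "DIVIDED", ]
    if (nrow(m) < 2) next
    lifespans <- m$end_time_h - m$birth_time_h
    # with sd 0 and w = 1 every division wait in a tree equals the root trait
    expect_lt(max(lifespans) - min(lifespans), 1e-9)
  }
})

test_that("resistant lineages never die and inherit resistance", {
  cfg <- quick_cfg(death_hazard_apoptotic = 0.1, death_hazard_necrotic = 0.1,
                   resistant_fraction = 0.5, duration_h = 30)
  ds <- simulate_forest(cfg, seed = 77)
  fo <- build_forest(ds)
  cls <- classify_trees(fo)
  # with hazards this high every non-resistant tree sees a death
  expect_true(any(cls$no_death))
  for (r in cls$root[cls$no_death]) {
    m <- ds$cells[ds$cells$cell_id %in% fo$trees[[r]], ]
    expect_false(any(m$fate %in% c("DEATH_APOPTOTIC", "DEATH_NECROTIC")))
  }
})

test_that("sister velocity coupling yields positive cross-displacement", {
  base <- list(duration_h = 18, n_roots = 150, division_mean_h = 6,
               division_trait_sd_h = 0.5, division_sd_h = 0.5,
               death_hazard_apoptotic = 0, death_hazard_necrotic = 0,
               resistant_fraction = 0, noise_sd = 0, diffusion = 100,
               persistence_h = 3, field_w = 4000, field_h = 4000)
  ds_c <- simulate_forest(do.call(sim_config,
                                  c(base, sister_coupling = 0.9)), seed = 5)
  ds_i <- simulate_forest(do.call(sim_config,
                                  c(base, sister_coupling = 0)), seed = 5)
  cross_at <- function(ds, t) {
    sis <- first_generation_sisters(build_forest(ds))
    cc <- sibling_cross_msd(ds, sis, t_max = t, step = 1, smoothing = FALSE)
    cc[nrow(cc), ]
  }
  c_c <- cross_at(ds_c, 4)
  c_i <- cross_at(ds_i, 4)
  expect_gt(c_c$n_pairs, 50)
  # coupled sisters co-move; independent ones average near zero
  expect_gt(c_c$mean_c12, 0)
  expect_gt(c_c$mean_c12, 5 * abs(c_i$mean_c12) - 200)
})

test_that("position perturbation is reproducible and zero-noise is identity", {
  ds <- simulate_forest(quick_cfg(n_roots = 5), seed = 2)
  p1 <- perturb_positions(ds, sd = 2, seed = 10)
  p2 <- perturb_positions(ds, sd = 2, seed = 10)
  expect_identical(p1$tracks, p2$tracks)
  expect_false(identical(p1$tracks$x, ds$tracks$x))
  expect_equal(mean(abs(p1$tracks$x - ds$tracks$x)), 2 * sqrt(2 / pi),
               tolerance = 0.1)
  expect_identical(perturb_positions(ds, sd = 0), ds)
})
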