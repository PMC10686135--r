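# Pedigree forests, frame selection, tree classification, growth curves.

test_that("forest groups cells into disjoint trees in preorder", {
  ds <- division_dataset()
  fo <- build_forest(ds)
  expect_s3_class(fo, "pedigree_forest")
  expect_named(fo$trees, "A")
  expect_identical(fo$trees$A, c("A", "Aa", "Ab"))

  ds2 <- simulate_forest(quick_cfg(), seed = 11)
  fo2 <- build_forest(ds2)
  members <- unlist(fo2$trees, use.names = FALSE)
  expect_identical(sort(members), sort(ds2$cells$cell_id))
  expect_equal(anyDuplicated(members), 0)
})

test_that("forest construction rejects cyclic parent links", {
  ds <- division_dataset()
  ds$cells$parent_id[ds$cells$cell_id == "A"] <- "Aa"  # cycle A <-> Aa
  # no root exists any more for that component
  expect_error(build_forest(
    tracking_dataset(ds$tracks, ds$cells, check = FALSE, duration_h = 20)),
    class = "tf_lineage_error")
})

test_that("frame selection matches a brute-force oracle", {
  set.seed(42)
  n_all <- 60; n_want <- 25
  specs <- data.frame(cell_id = sprintf("R%02d", seq_len(n_all)),
                      parent_id = NA_character_, birth = 0, end = 1,
                      fate = "ALIVE_AT_END",
                      x0 = runif(n_all, 0, 800), y0 = runif(n_all, 0, 600),
                      vx = 0, vy = 0)
  ds <- make_linear_dataset(specs)
  sel <- select_root_frame(ds, n = n_want)
  expect_length(sel$roots, n_want)

  # oracle: grow a centered frame over a fine scale grid and take the
  # smallest scale at which >= n roots are inside
  cx <- (min(specs$x0) + max(specs$x0)) / 2
  cy <- (min(specs$y0) + max(specs$y0)) / 2
  hw <- (max(specs$x0) - min(specs$x0)) / 2
  hh <- (max(specs$y0) - min(specs$y0)) / 2
  inside_at <- function(s)
    specs$cell_id[abs(specs$x0 - cx) <= s * hw + 1e-12 &
                  abs(specs$y0 - cy) <= s * hh + 1e-12]
  s_grid <- seq(0, 1, by = 1e-4)
  s_star <- s_grid[which(vapply(s_grid, function(s)
    length(inside_at(s)), numeric(1)) >= n_want)[1]]
  expect_equal(sel$scale, s_star, tolerance = 1e-4)
  expect_setequal(sel$roots, inside_at(sel$scale))
})

test_that("frame selection keeps boundary ties", {
  # four roots at the corners of a square around the centre plus one centre
  # cell: at the minimal scale all four corners enter together
  specs <- data.frame(cell_id = c("C", "N", "S", "E", "W"),
                      parent_id = NA_character_, birth = 0, end = 1,
                      fate = "ALIVE_AT_END",
                      x0 = c(50, 50, 50, 90, 10),
                      y0 = c(50, 90, 10, 50, 50), vx = 0, vy = 0)
  ds <- make_linear_dataset(specs)
  sel <- select_root_frame(ds, n = 2)
  expect_setequal(sel$roots, c("C", "N", "S", "E", "W"))
})

test_that("tree classes reflect the fates of the members", {
  # tree 1: both daughters survive; tree 2: one daughter dies -> still
  # surviving but not death-free; tree 3: extinct
  specs <- data.frame(
    cell_id = c("A", "Aa", "Ab", "B", "Ba", "Bb", "C"),
    parent_id = c(NA, "A", "A", NA, "B", "B", NA),
    birth = c(0, 5, 5, 0, 6, 6, 0),
    end = c(5, 20, 20, 6, 20, 12, 9),
    fate = c("DIVIDED", "ALIVE_AT_END", "ALIVE_AT_END",
             "DIVIDED", "ALIVE_AT_END", "DEATH_APOPTOTIC",
             "DEATH_NECROTIC"),
    x0 = 50, y0 = 50, vx = 0, vy = 0)
  fo <- build_forest(make_linear_dataset(specs, duration = 20))
  cls <- classify_trees(fo)
  expect_identical(cls$class, c("SURVIVING", "SURVIVING", "EXTINCT"))
  expect_identical(cls$no_death, c(TRUE, FALSE, FALSE))
})

test_that("synchronous doubling yields an exact exponential staircase", {
  ds <- simulate_forest(deterministic_cfg(T = 8, duration = 24, n_roots = 4),
                        seed = 1)
  fo <- build_forest(ds)
  gc <- population_growth_curve(fo, step = 1)
  # divisions at 8 and 16 h double the population each time
  expect_equal(gc$percent[gc$time_h == 4], 100)
  expect_equal(gc$percent[gc$time_h == 12], 200)
  expect_equal(gc$percent[gc$time_h == 20], 400)
  # half-open convention: the mother is not counted at its division instant
  expect_equal(gc$percent[gc$time_h == 8], 200)
})

test_that("post-division alignment averages per-tree staircases", {
  # two trees dividing at different times; each aligned curve jumps from
  # 200 to 400 at its own second division, so the average is exact
  specs <- data.frame(
    cell_id = c("A", "Aa", "Ab", "B", "Ba", "Bb"),
    parent_id = c(NA, "A", "A", NA, "B", "B"),
    birth = c(0, 4, 4, 0, 9, 9),
    end = c(4, 30, 30, 9, 30, 30),
    fate = c("DIVIDED", rep("ALIVE_AT_END", 2),
             "DIVIDED", rep("ALIVE_AT_END", 2)),
    x0 = 50, y0 = 50, vx = 0, vy = 0)
  fo <- build_forest(make_linear_dataset(specs, duration = 30))
  gc <- population_growth_curve(fo, mode = "post_first_division", step = 1)
  expect_equal(gc$percent[1], 200)
  expect_true(all(gc$percent == 200))
  expect_equal(attr(gc, "mode"), "post_first_division")
  # tree B runs out of recording 5 h earlier on the aligned clock
  expect_equal(max(gc$time_h), 30 - 4)
  expect_equal(gc$n_trees[gc$time_h <= 21], rep(2L, sum(gc$time_h <= 21)))
})

test_that("the cubic fit matches closed-form normal equations", {
  t <- seq(0, 90, by = 0.5)
  truth <- c(a = 2, b = 0.05, c = -0.001)
  curve <- data.frame(time_h = t,
                      percent = 100 + truth["a"] * t + truth["b"] * t^2 +
                        truth["c"] * t^3)
  fit <- fit_growth_polynomial(curve)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  # noisy case against an explicit least-squares oracle
  set.seed(9)
  curve$percent <- curve$percent + rnorm(length(t), sd = 3)
  fit2 <- fit_growth_polynomial(curve)
  X <- cbind(t, t^2, t^3)
  beta <- solve(crossprod(X), crossprod(X, curve$percent - 100))
  expect_equal(unname(coef(fit2)), as.numeric(beta), tolerance = 1e-8)
  expect_equal(unname(predict(fit2, newdata = 0)), 100)
})

test_that("growth export round-trips curve and coefficients", {
  ds <- simulate_forest(deterministic_cfg(), seed = 2)
  fo <- build_forest(ds)
  gc <- population_growth_curve(fo, step = 1)
  fit <- fit_growth_polynomial(gc)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".json")
  export_growth(gc, p1)
  export_growth(fit, p2)
  back <- utils::read.csv(p1)
  expect_equal(back$percent, gc$percent, tolerance = 1e-9)
  js <- jsonlite::read_json(p2)
  expect_equal(js$a, unname(coef(fit)["a"]), tolerance = 1e-12)
  expect_identical(js$mode, "from_start")
})
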