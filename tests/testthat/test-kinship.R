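# Sister-pair statistics, joint densities, displacement curves, PRW fit.

# two trees: A divides early and its daughters proliferate unevenly,
# B divides late (outside a 5 h admission window)
kin_fixture <- function() {
  specs <- data.frame(
    cell_id = c("A", "Aa", "Ab", "Aaa", "Aab", "B", "Ba", "Bb"),
    parent_id = c(NA, "A", "A", "Aa", "Aa", NA, "B", "B"),
    birth = c(0, 3, 3, 10, 10, 0, 8, 8),
    end = c(3, 10, 30, 30, 30, 8, 30, 30),
    fate = c("DIVIDED", "DIVIDED", "ALIVE_AT_END", "ALIVE_AT_END",
             "ALIVE_AT_END", "DIVIDED", "ALIVE_AT_END", "ALIVE_AT_END"),
    x0 = 50, y0 = 50, vx = c(0, 1, -1, 1, 2, 0, 0.5, -0.5), vy = 0)
  make_linear_dataset(specs, duration = 30)
}

test_that("sister admission respects the birth window", {
  ds <- kin_fixture()
  fo <- build_forest(ds)
  all_sis <- first_generation_sisters(fo)
  expect_equal(nrow(all_sis), 2)
  early <- first_generation_sisters(fo, birth_window = 5)
  expect_equal(early$mother_id, "A")
  expect_identical(sort(c(early$daughter1, early$daughter2)),
                   c("Aa", "Ab"))
})

test_that("descendant counts distinguish the two sister subtrees", {
  fo <- build_forest(kin_fixture())
  pr <- sister_descendant_pairs(fo, horizon = 20, birth_window = 5)
  expect_equal(nrow(pr), 1)
  # Aa has descendants Aaa, Aab born at 10 <= 3 + 20; Ab has none
  expect_setequal(c(pr$value1, pr$value2), c(2, 0))
  # a horizon before the grand-daughters' birth removes them
  pr2 <- sister_descendant_pairs(fo, horizon = 5, birth_window = 5)
  expect_equal(c(pr2$value1, pr2$value2), c(0, 0))
})

test_that("subtree track length sums straight-line distances", {
  fo <- build_forest(kin_fixture())
  ds <- kin_fixture()
  pr <- subtree_length_pairs(fo, ds, horizon = 27, birth_window = 5)
  # daughter Ab: speed 1 from t=3 to 30 -> length 27
  # daughter Aa: speed 1 on [3,10] (7) + Aaa speed 1 on [10,30] (20)
  #              + Aab speed 2 on [10,30] (40) -> 67
  # the smoother slightly shortens each segment at its ends (edge bias of
  # order the bandwidth), so compare within a few percent
  expect_equal(sort(c(pr$value1, pr$value2)), c(27, 67), tolerance = 0.05)
  # truncating at horizon 12 h cuts every track at t = 15
  pr2 <- subtree_length_pairs(fo, ds, horizon = 12, birth_window = 5)
  expect_equal(sort(c(pr2$value1, pr2$value2)), c(12, 7 + 5 + 10),
               tolerance = 0.05)
})

test_that("the smoothed pair histogram conserves mass and is symmetric", {
  set.seed(13)
  n <- 40
  pairs <- new_sister_pairs(
    data.frame(mother_id = sprintf("M%02d", 1:n),
               value1 = rpois(n, 6), value2 = rpois(n, 6),
               birth_time_h = 0),
    "descendant_count")
  jd <- smoothed_pair_histogram(pairs, bandwidth = 1.5)
  expect_equal(jd$mass, 2 * n, tolerance = 1e-9)
  # symmetrization makes z(v1,v2) == z(v2,v1) on the common grid
  expect_equal(jd$z, t(jd$z), tolerance = 1e-9)
})

test_that("the Scott-rule KDE integrates to one and finds two clusters", {
  set.seed(8)
  cl1 <- matrix(rnorm(160, mean = 0, sd = 1), ncol = 2)
  cl2 <- matrix(rnorm(160, mean = 8, sd = 1), ncol = 2)
  jd <- joint_kde(rbind(cl1, cl2), grid_n = 96, pad_bw = 4)
  expect_equal(jd$integral, 1, tolerance = 0.02)
  expect_equal(as.integer(count_local_maxima(jd, min_height = 0.2)), 2L)
  # a single blob has a single mode
  jd1 <- joint_kde(cl1, grid_n = 64, pad_bw = 4)
  expect_equal(as.integer(count_local_maxima(jd1, min_height = 0.2)), 1L)
})

test_that("pair correlation is order-invariant and exact on a known set", {
  pairs <- new_sister_pairs(
    data.frame(mother_id = c("M1", "M2", "M3", "M4"),
               value1 = c(1, 2, 3, 4), value2 = c(2, 1, 4, 3),
               birth_time_h = 0),
    "descendant_count")
  r <- pair_correlation(pairs)
  swapped <- pairs
  swapped$value1 <- pairs$value2
  swapped$value2 <- pairs$value1
  expect_equal(as.numeric(pair_correlation(swapped)), as.numeric(r))
  # oracle: Pearson correlation of the symmetrized 8-point set
  v1 <- c(1, 2, 3, 4, 2, 1, 4, 3); v2 <- c(2, 1, 4, 3, 1, 2, 3, 4)
  expect_equal(as.numeric(r), cor(v1, v2))
  expect_equal(attr(r, "n"), 4)
})

test_that("ballistic motion gives a quadratic displacement curve", {
  specs <- data.frame(
    cell_id = c("A", "B"), parent_id = NA_character_, birth = 0, end = 20,
    fate = "ALIVE_AT_END", x0 = c(0, 100), y0 = 0, vx = c(2, 0),
    vy = c(0, 3))
  ds <- make_linear_dataset(specs, duration = 20)
  mc <- msd_curves(ds, c("A", "B"), t_max = 10, step = 1, smoothing = FALSE)
  # c(t) = v^2 t^2, averaged over speeds 2 and 3 -> 6.5 t^2
  expect_equal(mc$curve$mean_c, 6.5 * mc$curve$t_h^2, tolerance = 1e-9)
  expect_equal(mc$curve$n, rep(2L, 10))
  # attrition: shorten B's coverage and n drops after its end
  specs$end[2] <- 5
  ds2 <- make_linear_dataset(specs, duration = 20)
  mc2 <- msd_curves(ds2, c("A", "B"), t_max = 10, step = 1,
                    smoothing = FALSE)
  expect_equal(mc2$curve$n, c(rep(2L, 5), rep(1L, 5)))
})

test_that("sibling cross-displacement is exact for mirrored sisters", {
  # sisters moving in exactly opposite directions: c12(t) = -v^2 t^2
  ds <- division_dataset(t_div = 2, dur = 20, v = c(1, -1))
  sis <- first_generation_sisters(build_forest(ds))
  cc <- sibling_cross_msd(ds, sis, t_max = 10, step = 1, smoothing = FALSE)
  expect_equal(cc$mean_c12, -cc$t_h^2, tolerance = 1e-9)
  expect_equal(cc$n_pairs, rep(1L, 10))
  # co-moving sisters flip the sign
  ds2 <- division_dataset(t_div = 2, dur = 20, v = c(1, 1))
  cc2 <- sibling_cross_msd(ds2, first_generation_sisters(build_forest(ds2)),
                           t_max = 10, step = 1, smoothing = FALSE)
  expect_equal(cc2$mean_c12, cc2$t_h^2, tolerance = 1e-9)
})

test_that("the memory-time fit recovers a noiseless Fuerth curve", {
  P0 <- 3; D0 <- 50
  t <- seq(0.5, 15, by = 0.5)
  cur <- data.frame(t_h = t,
                    mean_c = 4 * D0 * (t - P0 * (1 - exp(-t / P0))))
  fit <- estimate_memory_time(cur)
  expect_equal(fit$P, P0, tolerance = 1e-4)
  expect_equal(fit$D, D0, tolerance = 1e-4)
  expect_equal(fit$censored, "none")
  expect_lt(fit$rss, 1e-6)
})

test_that("a linear displacement curve censors the fit at the lower bound", {
  t <- seq(0.5, 15, by = 0.5)
  fit <- estimate_memory_time(data.frame(t_h = t, mean_c = 400 * t))
  expect_equal(fit$censored, "lower")
})
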