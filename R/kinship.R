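# Sister-cell and lineage-downstream statistics: joint distributions of
# subtree descendant counts and track lengths, symmetrized correlation,
# mean squared displacement (MSD), sibling cross-displacement, and a
# persistent-random-walk fit of the directional memory time.

#' First-generation sister pairs of a forest
#'
#' The first division of a tree is its root's division; the two daughters
#' are the tree's first-generation sisters.
#'
#' @param forest a [build_forest()] result.
#' @param birth_window only trees whose first division occurs within this
#'   many hours after the start of recording are returned (default `Inf`).
#' @return data.frame with `mother_id`, `daughter1`, `daughter2`,
#'   `birth_time_h` (the sisters' common birth time).
#' @export
first_generation_sisters <- function(forest, birth_window = Inf) {
  cl <- forest$cells
  out <- lapply(names(forest$trees), function(r) {
    root <- cl[cl$cell_id == r, , drop = FALSE]
    if (root$fate != "DIVIDED" || root$end_time_h > birth_window)
      return(NULL)
    d <- cl$cell_id[!is.na(cl$parent_id) & cl$parent_id == r]
    d <- sort(d)
    data.frame(mother_id = r, daughter1 = d[1], daughter2 = d[2],
               birth_time_h = root$end_time_h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(mother_id = character(), daughter1 = character(),
                      daughter2 = character(), birth_time_h = numeric())
  rownames(out) <- NULL
  out
}

# all descendants (excluding the cell itself) of `id` in the cell table
descendants_of <- function(cells, id) {
  kids <- split(cells$cell_id, factor(cells$parent_id,
                                      levels = cells$cell_id))
  acc <- character(0)
  stack <- kids[[id]]
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    acc <- c(acc, cur)
    ch <- kids[[cur]]
    if (length(ch) > 0) stack <- c(stack, ch)
  }
  acc
}

new_sister_pairs <- function(df, statistic) {
  rownames(df) <- NULL
  structure(df, statistic = statistic,
            class = c("sister_pairs", "data.frame"))
}

#' Descendant counts of first-generation sister subtrees
#'
#' For every root that divides within `birth_window` hours of the start of
#' recording, counts for each of the two daughters the number of distinct
#' descendant cells (the daughter itself excluded) born within `horizon`
#' hours of the daughters' birth. The count is cumulative — cells ever
#' born, not cells alive at the horizon. Comparing the two values of a
#' pair probes inheritance of proliferative capacity from the common
#' mother.
#'
#' @param forest a [build_forest()] result.
#' @param horizon counting horizon after the sisters' birth, hours
#'   (default 70).
#' @param birth_window admit only sisters born within this many hours after
#'   the start of recording (default 20).
#' @param count `"born"` (default, cumulative) or `"alive"` (descendants
#'   alive at the horizon).
#' @return Object of class `sister_pairs`: data.frame with `mother_id`,
#'   `value1`, `value2`, `birth_time_h`; values stored in canonical
#'   (daughter-id) order, analyses symmetrize.
#' @export
sister_descendant_pairs <- function(forest, horizon = 70, birth_window = 20,
                                    count = c("born", "alive")) {
  count <- match.arg(count)
  if (horizon <= 0 || birth_window <= 0)
    tf_error("tf_input_error", "horizon and birth_window must be positive")
  sis <- first_generation_sisters(forest, birth_window)
  cl <- forest$cells
  val <- function(daughter, t_birth) {
    dd <- descendants_of(cl, daughter)
    if (length(dd) == 0) return(0L)
    d <- cl[match(dd, cl$cell_id), , drop = FALSE]
    if (count == "born")
      sum(d$birth_time_h <= t_birth + horizon + TF_TIME_TOL)
    else
      sum(alive_at(d, t_birth + horizon))
  }
  df <- sis
  df$value1 <- vapply(seq_len(nrow(sis)), function(i)
    as.numeric(val(sis$daughter1[i], sis$birth_time_h[i])), numeric(1))
  df$value2 <- vapply(seq_len(nrow(sis)), function(i)
    as.numeric(val(sis$daughter2[i], sis$birth_time_h[i])), numeric(1))
  new_sister_pairs(df[, c("mother_id", "value1", "value2", "birth_time_h")],
                   "descendant_count")
}

#' Total subtree track length of first-generation sister subtrees
#'
#' For each daughter of a qualifying first division, sums the smoothed
#' track length of the daughter and of every descendant, each cell's
#' contribution truncated to the interval from its own birth to `horizon`
#' hours after the sisters' birth. The pair of sums is the joint "size in
#' motion" of the two sister subtrees.
#'
#' @param forest a [build_forest()] result.
#' @param ds the [tracking_dataset()] the forest was built from.
#' @param horizon length horizon after the sisters' birth, hours
#'   (default 60).
#' @param birth_window admit only sisters born within this many hours after
#'   the start of recording (default 30).
#' @param bandwidth smoothing bandwidth for [smooth_trajectory()], hours.
#' @param truncate if `TRUE` (default) each descendant's track is cut at
#'   the horizon; if `FALSE`, whole lifespans of cells born before the
#'   horizon are included.
#' @return A `sister_pairs` object (see [sister_descendant_pairs()]).
#' @export
subtree_length_pairs <- function(forest, ds, horizon = 60, birth_window = 30,
                                 bandwidth = 0.25, truncate = TRUE) {
  sis <- first_generation_sisters(forest, birth_window)
  cl <- forest$cells
  tr_by_cell <- split(seq_len(nrow(ds$tracks)), ds$tracks$cell_id)
  step <- ds$metadata$frame_interval_h
  subtree_len <- function(daughter, t_birth) {
    ids <- c(daughter, descendants_of(cl, daughter))
    t_hi <- t_birth + horizon
    total <- 0
    for (id in ids) {
      rec <- cl[cl$cell_id == id, , drop = FALSE]
      if (rec$birth_time_h >= t_hi - TF_TIME_TOL && truncate) next
      pts <- ds$tracks[tr_by_cell[[id]], , drop = FALSE]
      if (is.null(pts) || nrow(pts) < 2) next
      st <- tryCatch(smooth_trajectory(pts, bandwidth),
                     tf_degenerate_track = function(e)
                       tf_error("tf_degenerate_track",
                                "cell %s: %s", id, conditionMessage(e)))
      t0 <- st$t_min
      t1 <- if (truncate) min(st$t_max, t_hi) else st$t_max
      if (t1 > t0 + TF_TIME_TOL)
        total <- total + track_length(st, t0, t1, step = step)
    }
    total
  }
  df <- sis
  df$value1 <- vapply(seq_len(nrow(sis)), function(i)
    subtree_len(sis$daughter1[i], sis$birth_time_h[i]), numeric(1))
  df$value2 <- vapply(seq_len(nrow(sis)), function(i)
    subtree_len(sis$daughter2[i], sis$birth_time_h[i]), numeric(1))
  new_sister_pairs(df[, c("mother_id", "value1", "value2", "birth_time_h")],
                   "subtree_track_length")
}

# unordered pairs -> symmetrized point set {(v1,v2),(v2,v1)}
symmetrize_pairs <- function(pairs) {
  cbind(v1 = c(pairs$value1, pairs$value2),
        v2 = c(pairs$value2, pairs$value1))
}

#' Gaussian-smoothed joint histogram of sister pairs
#'
#' Histograms the symmetrized pairs on the integer lattice and convolves
#' with an isotropic Gaussian of standard deviation `bandwidth` (lattice
#' units; the kernel is truncated at 4 bandwidths and renormalized, so the
#' total smoothed mass equals twice the number of pairs to within 1e-6).
#' Designed for count-valued pair statistics; local maxima off/on the
#' diagonal reveal clusters of lineage behavior.
#'
#' @param pairs a `sister_pairs` object (count-valued), at least one pair.
#' @param bandwidth Gaussian standard deviation in lattice units
#'   (default 1.5).
#' @return Object of class `joint_density`: list with `v1`, `v2` (grid
#'   coordinates), `z` (matrix of smoothed counts, rows indexed by `v1`),
#'   `method = "gaussian_smoothed_histogram"`, `bandwidth`, `mass`.
#' @export
smoothed_pair_histogram <- function(pairs, bandwidth = 1.5) {
  if (nrow(pairs) == 0)
    tf_error("tf_input_error", "no sister pairs to histogram")
  pts <- round(symmetrize_pairs(pairs))
  r <- ceiling(4 * bandwidth)
  v1 <- seq(min(pts[, 1]) - r, max(pts[, 1]) + r)
  v2 <- seq(min(pts[, 2]) - r, max(pts[, 2]) + r)
  H <- matrix(0, length(v1), length(v2))
  i <- match(pts[, 1], v1)
  j <- match(pts[, 2], v2)
  for (k in seq_along(i)) H[i[k], j[k]] <- H[i[k], j[k]] + 1
  ker <- stats::dnorm(seq(-r, r), sd = bandwidth)
  ker <- ker / sum(ker)
  # separable convolution, zero-padded; mass stays inside because the grid
  # already carries a margin of r cells
  conv1 <- function(M) apply(M, 2, function(col)
    stats::convolve(col, rev(ker), type = "open")[(r + 1):(r + length(col))])
  Z <- t(conv1(t(conv1(H))))
  structure(list(v1 = v1, v2 = v2, z = Z,
                 method = "gaussian_smoothed_histogram",
                 bandwidth = bandwidth, mass = sum(Z)),
            class = "joint_density")
}

#' Joint kernel density estimate of sister pairs (Scott bandwidth)
#'
#' Gaussian product KDE on the symmetrized pair set with the Scott rule:
#' the kernel covariance is the empirical covariance of the symmetrized
#' sample scaled by n^(-2/(d+4)) with d = 2, n the symmetrized sample
#' size. The density is evaluated on a rectangular grid extending
#' `pad_bw` marginal bandwidths beyond the data range and integrates to 1
#' over that grid to within about 2%.
#'
#' @param pairs a `sister_pairs` object with at least 3 pairs, or a
#'   two-column matrix of points (already symmetric or not — a matrix is
#'   used as-is).
#' @param grid_n grid resolution per axis (default 96).
#' @param pad_bw grid margin in marginal bandwidths (default 3).
#' @return A `joint_density` (see [smoothed_pair_histogram()]) with
#'   `method = "kde_scott"`, `bandwidth` (the 2x2 kernel covariance) and
#'   `integral` (the grid integral of the density).
#' @export
joint_kde <- function(pairs, grid_n = 96, pad_bw = 3) {
  pts <- if (is.matrix(pairs)) pairs else {
    if (nrow(pairs) < 3)
      tf_error("tf_input_error", "need at least 3 pairs for a KDE")
    symmetrize_pairs(pairs)
  }
  n <- nrow(pts)
  S <- stats::cov(pts)
  H <- S * n^(-2 / 6)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || min(ev) / max(ev) < 1e-12)
    tf_error("tf_rank_error", "degenerate pair covariance; KDE undefined")
  bw <- sqrt(diag(H))
  v1 <- seq(min(pts[, 1]) - pad_bw * bw[1], max(pts[, 1]) + pad_bw * bw[1],
            length.out = grid_n)
  v2 <- seq(min(pts[, 2]) - pad_bw * bw[2], max(pts[, 2]) + pad_bw * bw[2],
            length.out = grid_n)
  Hinv <- solve(H)
  dethalf <- sqrt(det(H))
  g <- as.matrix(expand.grid(v1 = v1, v2 = v2))
  z <- numeric(nrow(g))
  for (k in seq_len(n)) {
    d1 <- g[, 1] - pts[k, 1]
    d2 <- g[, 2] - pts[k, 2]
    q <- Hinv[1, 1] * d1^2 + 2 * Hinv[1, 2] * d1 * d2 + Hinv[2, 2] * d2^2
    z <- z + exp(-0.5 * q)
  }
  z <- z / (n * 2 * pi * dethalf)
  Z <- matrix(z, grid_n, grid_n)        # rows follow v1, columns v2
  integral <- sum(Z) * diff(v1[1:2]) * diff(v2[1:2])
  structure(list(v1 = v1, v2 = v2, z = Z, method = "kde_scott",
                 bandwidth = H, integral = integral),
            class = "joint_density")
}

#' @export
print.joint_density <- function(x, ...) {
  cat(sprintf("joint_density (%s): %d x %d grid", x$method,
              length(x$v1), length(x$v2)))
  if (!is.null(x$integral)) cat(sprintf(", integral %.4f", x$integral))
  if (!is.null(x$mass)) cat(sprintf(", mass %.6g", x$mass))
  cat("\n")
  invisible(x)
}

#' Count strict local maxima of a joint density
#'
#' A grid cell is a local maximum if it strictly exceeds all of its 8
#' neighbours and carries at least `min_height` times the global maximum.
#' Used to detect multi-modal (clustered) sister-pair distributions.
#'
#' @param jd a `joint_density`.
#' @param min_height relative height threshold (default 0.05).
#' @return Number of local maxima; their grid coordinates as attribute
#'   `"peaks"` (data.frame `v1`, `v2`, `height`).
#' @export
count_local_maxima <- function(jd, min_height = 0.05) {
  Z <- jd$z
  nr <- nrow(Z); nc <- ncol(Z)
  thr <- min_height * max(Z)
  peaks <- list()
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- Z[i, j]
    if (v < thr) next
    nb <- Z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v > max(nb[-5]))
      peaks[[length(peaks) + 1L]] <-
        data.frame(v1 = jd$v1[i], v2 = jd$v2[j], height = v)
  }
  n <- length(peaks)
  attr(n, "peaks") <- if (n > 0) do.call(rbind, peaks) else
    data.frame(v1 = numeric(), v2 = numeric(), height = numeric())
  n
}

#' Pearson correlation of symmetrized sister pairs
#'
#' Product-moment correlation on the symmetrized point set
#' \{(v1, v2), (v2, v1)\}. Symmetrization makes the result invariant to
#' within-pair order and forces equal marginal means and variances; a
#' positive value reflects inheritance of the statistic from the common
#' mother.
#'
#' @param pairs a `sister_pairs` object with at least 3 pairs.
#' @return Correlation in `[-1, 1]`, with attribute `n` (number of pairs).
#' @export
pair_correlation <- function(pairs) {
  if (nrow(pairs) < 3)
    tf_error("tf_input_error", "need at least 3 pairs for a correlation")
  pts <- symmetrize_pairs(pairs)
  if (stats::var(pts[, 1]) == 0 || stats::var(pts[, 2]) == 0)
    tf_error("tf_undefined_correlation",
             "zero variance: correlation undefined")
  r <- stats::cor(pts[, 1], pts[, 2])
  attr(r, "n") <- nrow(pairs)
  r
}

# position of one cell at arbitrary times, either kernel-smoothed or
# linearly interpolated raw observations; NA outside the validity window
# [lo, hi] (the cell's lifespan). Query times inside the lifespan but
# outside the observed span — a cell's birth falls up to one frame before
# its first observation — are clamped to the nearest observation time.
cell_positions_at <- function(pts, times, bandwidth, smoothing,
                              lo = min(pts$time_h), hi = max(pts$time_h)) {
  t_lo <- min(pts$time_h); t_hi <- max(pts$time_h)
  ok <- times >= lo - TF_TIME_TOL & times <= hi + TF_TIME_TOL
  out <- matrix(NA_real_, length(times), 2, dimnames = list(NULL, c("x", "y")))
  if (!any(ok)) return(out)
  tt <- pmin(pmax(times[ok], t_lo), t_hi)
  if (smoothing) {
    st <- smooth_trajectory(pts, bandwidth)
    p <- predict(st, tt)
    out[ok, ] <- cbind(p$x, p$y)
  } else {
    out[ok, 1] <- stats::approx(pts$time_h, pts$x, xout = tt)$y
    out[ok, 2] <- stats::approx(pts$time_h, pts$y, xout = tt)$y
  }
  out
}

#' Mean squared displacement from birth for a cell cohort
#'
#' For each cell, r(t) is the displacement of its position t hours after
#' birth relative to its position at birth, and c(t) = r(t)·r(t) is the
#' squared displacement. The curve reports the cohort mean of c(t) and of
#' c(t)/t at each grid time; cells that die, divide or lose coverage
#' before birth + t simply drop out of the mean there (`n` exposes the
#' attrition). For memory-less Brownian motion the mean of c(t)/t is flat;
#' a rising initial segment reveals directional persistence.
#'
#' Positions are kernel-smoothed by default. Time-averaging over a
#' bandwidth h contracts squared displacements by a constant of order
#' 6.4·D·h for diffusive motion, so for noise-free synthetic data
#' `smoothing = FALSE` (linear interpolation of the exact positions) is
#' the unbiased choice; smoothing pays off when positional measurement
#' noise dominates.
#'
#' @param ds a [tracking_dataset()].
#' @param cell_ids cohort of cells (e.g. first-generation daughters).
#' @param t_max maximum time since birth, hours (default 15).
#' @param step grid step, hours (default 0.5).
#' @param bandwidth smoothing bandwidth, hours.
#' @param smoothing use kernel-smoothed positions (default `TRUE`).
#' @return Object of class `displacement_curves`: list with `curve`
#'   (data.frame `t_h`, `mean_c`, `mean_c_over_t`, `n`) and `per_cell`
#'   (cells x grid matrix of c values, `NA` where a cell no longer
#'   contributes).
#' @export
msd_curves <- function(ds, cell_ids, t_max = 15, step = 0.5,
                       bandwidth = 0.25, smoothing = TRUE) {
  if (length(cell_ids) == 0)
    tf_error("tf_input_error", "empty cohort")
  cl <- ds$cells
  grid <- seq(step, t_max, by = step)
  tr_by_cell <- split(seq_len(nrow(ds$tracks)), ds$tracks$cell_id)
  C <- matrix(NA_real_, length(cell_ids), length(grid),
              dimnames = list(cell_ids, NULL))
  for (id in cell_ids) {
    pts <- ds$tracks[tr_by_cell[[id]], , drop = FALSE]
    if (is.null(pts) || nrow(pts) < 2) next
    j <- match(id, cl$cell_id)
    b <- cl$birth_time_h[j]
    pos <- cell_positions_at(pts, c(b, b + grid), bandwidth, smoothing,
                             lo = b, hi = cl$end_time_h[j])
    r <- sweep(pos[-1, , drop = FALSE], 2, pos[1, ])
    C[id, ] <- r[, 1]^2 + r[, 2]^2
  }
  n <- colSums(!is.na(C))
  mean_c <- ifelse(n > 0, colMeans(C, na.rm = TRUE), NA_real_)
  structure(list(curve = data.frame(t_h = grid, mean_c = mean_c,
                                    mean_c_over_t = mean_c / grid, n = n),
                 per_cell = C, step = step, smoothing = smoothing,
                 bandwidth = bandwidth),
            class = "displacement_curves")
}

#' @export
print.displacement_curves <- function(x, ...) {
  cat(sprintf("displacement_curves: %d cells, t up to %.3g h (step %.3g)\n",
              nrow(x$per_cell), max(x$curve$t_h), x$step))
  print(utils::head(x$curve, 4))
  invisible(x)
}

#' Sibling cross-displacement curve
#'
#' For each sister pair, the dot product c12(t) = r1(t)·r2(t) of the two
#' birth-relative displacement vectors t hours after the sisters' common
#' birth, averaged over pairs and divided by t. Positive values mean
#' sisters tend to move together after division; for independent walkers
#' the mean is zero. A pair contributes at t only while both sisters have
#' track coverage.
#'
#' @param ds a [tracking_dataset()].
#' @param sisters data.frame from [first_generation_sisters()] (columns
#'   `daughter1`, `daughter2`).
#' @inheritParams msd_curves
#' @return data.frame with `t_h`, `mean_c12`, `mean_c12_over_t`,
#'   `n_pairs`; attribute `per_pair` carries the pair x grid matrix.
#' @export
sibling_cross_msd <- function(ds, sisters, t_max = 15, step = 0.5,
                              bandwidth = 0.25, smoothing = TRUE) {
  if (nrow(sisters) == 0)
    tf_error("tf_input_error", "empty sister cohort")
  cl <- ds$cells
  grid <- seq(step, t_max, by = step)
  tr_by_cell <- split(seq_len(nrow(ds$tracks)), ds$tracks$cell_id)
  P <- matrix(NA_real_, nrow(sisters), length(grid))
  disp <- function(id, b) {
    pts <- ds$tracks[tr_by_cell[[id]], , drop = FALSE]
    if (is.null(pts) || nrow(pts) < 2) return(NULL)
    end <- cl$end_time_h[match(id, cl$cell_id)]
    pos <- cell_positions_at(pts, c(b, b + grid), bandwidth, smoothing,
                             lo = b, hi = end)
    sweep(pos[-1, , drop = FALSE], 2, pos[1, ])
  }
  for (i in seq_len(nrow(sisters))) {
    b <- cl$birth_time_h[cl$cell_id == sisters$daughter1[i]]
    r1 <- disp(sisters$daughter1[i], b)
    r2 <- disp(sisters$daughter2[i], b)
    if (is.null(r1) || is.null(r2)) next
    P[i, ] <- r1[, 1] * r2[, 1] + r1[, 2] * r2[, 2]
  }
  n <- colSums(!is.na(P))
  mean_c12 <- ifelse(n > 0, colMeans(P, na.rm = TRUE), NA_real_)
  out <- data.frame(t_h = grid, mean_c12 = mean_c12,
                    mean_c12_over_t = mean_c12 / grid, n_pairs = n)
  attr(out, "per_pair") <- P
  out
}

#' Estimate the directional memory (persistence) time
#'
#' Fits the persistent-random-walk (Fuerth) mean-squared-displacement form
#' \deqn{c(t) = 4D\,(t - P\,(1 - e^{-t/P}))}
#' to a cohort MSD curve by least squares. P is the memory time — how long
#' a cell tends to keep its direction of motion — and D the long-time
#' diffusion scale. For fixed P the optimal D is linear, so the fit is a
#' 1-D profile optimization over P on `[step, 10 t_max]`. A fit driven to
#' the lower bound (no resolvable persistence, Brownian limit) or beyond
#' `t_max` (ballistic-only window) is flagged as censored.
#'
#' @param curves a [msd_curves()] result (or a data.frame with `t_h` and
#'   `mean_c` on at least 6 grid points).
#' @return Object of class `prw_fit`: list with `P` (hours), `D` (length
#'   units squared per hour), `rss`, `censored` (`"none"`, `"lower"` or
#'   `"upper"`), `fitted`, `curve`.
#' @export
estimate_memory_time <- function(curves) {
  cur <- if (inherits(curves, "displacement_curves")) curves$curve else curves
  cur <- cur[is.finite(cur$mean_c), , drop = FALSE]
  if (nrow(cur) < 6)
    tf_error("tf_input_error",
             "need mean c(t) on at least 6 grid points, have %d", nrow(cur))
  t <- cur$t_h
  y <- cur$mean_c
  step <- min(diff(t))
  t_max <- max(t)
  gfun <- function(P) t - P * (1 - exp(-t / P))
  rss_of <- function(P) {
    g <- gfun(P)
    beta <- sum(g * y) / sum(g * g)      # beta = 4D, profiled out
    sum((y - beta * g)^2)
  }
  opt <- stats::optimize(rss_of, lower = step, upper = 10 * t_max,
                         tol = 1e-8)
  P <- opt$minimum
  # compare against the boundary values: optimize() never samples them
  for (Pb in c(step, 10 * t_max))
    if (rss_of(Pb) < opt$objective) {
      P <- Pb
      opt$objective <- rss_of(Pb)
    }
  g <- gfun(P)
  beta <- sum(g * y) / sum(g * g)
  censored <- if (P <= step * 1.001) "lower"
  else if (P >= t_max) "upper" else "none"
  structure(list(P = P, D = beta / 4, rss = sum((y - beta * g)^2),
                 censored = censored, fitted = beta * g,
                 curve = cur),
            class = "prw_fit")
}

#' @export
print.prw_fit <- function(x, digits = 4, ...) {
  cat("Persistent-random-walk MSD fit  c(t) = 4D (t - P (1 - exp(-t/P)))\n")
  cat(sprintf("  memory time P = %s h, D = %s, RSS = %.4g%s\n",
              signif(x$P, digits), signif(x$D, digits), x$rss,
              if (x$censored != "none")
                sprintf("  [censored at %s bound]", x$censored) else ""))
  invisible(x)
}

#' @export
coef.prw_fit <- function(object, ...) c(P = object$P, D = object$D)
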