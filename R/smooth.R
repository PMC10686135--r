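# Trajectory kinematics: Gaussian-kernel (Nadaraya-Watson) smoothing and
# interpolation of raw track points, speed from the analytic derivative of
# the smoother, track length, and moving generalized power means of speed.

#' Kernel-smooth one cell's trajectory
#'
#' Builds a Nadaraya-Watson estimate of the cell's position as a function
#' of time, with a Gaussian kernel of standard deviation `bandwidth`:
#' \deqn{\hat x(t) = \sum_i w_i(t) x_i / \sum_i w_i(t), \quad
#'       w_i(t) = \exp(-(t - t_i)^2 / (2 h^2)).}
#' The estimate is evaluable at any time inside the cell's lifespan,
#' including between frames, which both suppresses positional measurement
#' noise and interpolates over irregular sampling. The kernel is truncated
#' at 4 bandwidths (relative weight-mass error below 1e-4).
#'
#' @param points data.frame of one cell's track points (`time_h`, `x`, `y`;
#'   at least 2 rows).
#' @param bandwidth kernel standard deviation in hours; the default 0.25 h
#'   (15 min) suits 6-min frame intervals.
#' @return Object of class `smoothed_trajectory`: list with the sample
#'   times/positions, `bandwidth`, and the lifespan covered.
#' @seealso [predict.smoothed_trajectory()], [speed_series()],
#'   [track_length()]
#' @export
smooth_trajectory <- function(points, bandwidth = 0.25) {
  if (nrow(points) < 2)
    tf_error("tf_degenerate_track",
             "need at least 2 track points to smooth, have %d", nrow(points))
  o <- order(points$time_h)
  structure(list(t = points$time_h[o], x = points$x[o], y = points$y[o],
                 bandwidth = bandwidth,
                 t_min = min(points$time_h), t_max = max(points$time_h)),
            class = "smoothed_trajectory")
}

#' @export
print.smoothed_trajectory <- function(x, ...) {
  cat(sprintf("smoothed_trajectory: %d points on [%.3g, %.3g] h, bandwidth %.3g h\n",
              length(x$t), x$t_min, x$t_max, x$bandwidth))
  invisible(x)
}

# core evaluator: smoothed position and its analytic time-derivative at
# arbitrary times. Kernel truncated at +/- 4 bandwidths; all points used
# when none fall inside the window (very sparse tracks).
nw_eval <- function(st, times) {
  h <- st$bandwidth
  n <- length(times)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("x", "y", "dx", "dy")))
  for (k in seq_len(n)) {
    d <- st$t - times[k]
    use <- abs(d) <= 4 * h
    if (!any(use)) use <- rep(TRUE, length(d))
    d <- d[use]
    w <- exp(-d^2 / (2 * h^2))
    S <- sum(w)
    wp <- w * d / h^2            # dw/dt (note d = t_i - t)
    Sp <- sum(wp)
    xs <- st$x[use]; ys <- st$y[use]
    xhat <- sum(w * xs) / S
    yhat <- sum(w * ys) / S
    out[k, ] <- c(xhat, yhat,
                  (sum(wp * xs) - xhat * Sp) / S,
                  (sum(wp * ys) - yhat * Sp) / S)
  }
  out
}

#' Evaluate a smoothed trajectory
#'
#' @param object a [smooth_trajectory()] result.
#' @param times evaluation times in hours, inside the cell's lifespan.
#' @param ... unused.
#' @return data.frame with `time_h`, `x`, `y`, `vx`, `vy`, `speed` (the
#'   Euclidean norm of the analytic derivative of the position estimate).
#' @export
predict.smoothed_trajectory <- function(object, times = object$t, ...) {
  if (any(times < object$t_min - TF_TIME_TOL |
          times > object$t_max + TF_TIME_TOL))
    tf_error("tf_range_error",
             "evaluation time outside lifespan [%.6g, %.6g]",
             object$t_min, object$t_max)
  m <- nw_eval(object, times)
  data.frame(time_h = times, x = m[, "x"], y = m[, "y"],
             vx = m[, "dx"], vy = m[, "dy"],
             speed = sqrt(m[, "dx"]^2 + m[, "dy"]^2))
}

#' Speed series of a smoothed trajectory
#'
#' Speed is the norm of the analytic time-derivative of the
#' Nadaraya-Watson position estimate — not a finite difference of raw
#' points, whose magnitude would depend on the sampling resolution.
#'
#' @inheritParams predict.smoothed_trajectory
#' @param st a `smoothed_trajectory`.
#' @return data.frame with `time_h` and `speed` (length units per hour).
#' @export
speed_series <- function(st, times = st$t) {
  predict(st, times)[, c("time_h", "speed")]
}

#' Track length over an interval
#'
#' Arc length of the smoothed trajectory: the integral of smoothed speed
#' over `[t0, t1]`, by the trapezoid rule on a grid of step at most `step`.
#' Length is additive over abutting intervals and invariant to rigid
#' motions and to time reversal of the trajectory.
#'
#' @param st a `smoothed_trajectory`.
#' @param t0,t1 interval bounds in hours (default: whole lifespan).
#' @param step maximum integration step in hours (default 0.1, the frame
#'   interval of the motivating recordings).
#' @return Arc length in the trajectory's length units.
#' @export
track_length <- function(st, t0 = st$t_min, t1 = st$t_max, step = 0.1) {
  if (t0 >= t1)
    tf_error("tf_range_error", "need t0 < t1, got [%.6g, %.6g]", t0, t1)
  if (t0 < st$t_min - TF_TIME_TOL || t1 > st$t_max + TF_TIME_TOL)
    tf_error("tf_range_error",
             "interval [%.6g, %.6g] outside lifespan [%.6g, %.6g]",
             t0, t1, st$t_min, st$t_max)
  n <- max(2L, ceiling((t1 - t0) / step) + 1L)
  grid <- seq(t0, t1, length.out = n)
  v <- predict(st, grid)$speed
  sum(diff(grid) * (v[-1] + v[-n]) / 2)
}

#' Moving generalized power mean of speed
#'
#' For each window center t, the order-p power mean
#' \eqn{M_p = (\mathrm{mean}_{|s-t|\le w/2}\, v(s)^p)^{1/p}} of the speed
#' samples in the centered window. Larger p weights the highest speeds more
#' (M_p is non-decreasing in p), so the pair (M_1, M_4) compactly separates
#' steadily-moving cells from cells with speed bursts. Centers are
#' restricted to where the full window fits inside the sampled span.
#'
#' @param speed data.frame with `time_h` and `speed` (e.g. from
#'   [speed_series()]).
#' @param p power-mean order, `p >= 1`.
#' @param window window width in hours (default 8).
#' @return Object of class `power_mean_series`: data.frame with `time_h`
#'   (window centers) and `m_p`; attributes `p` and `window`. Zero rows if
#'   no full window fits.
#' @export
moving_power_mean <- function(speed, p = 1, window = 8) {
  if (p < 1) tf_error("tf_input_error", "power-mean order p must be >= 1")
  if (window <= 0) tf_error("tf_input_error", "window must be positive")
  tt <- speed$time_h
  v <- speed$speed
  half <- window / 2
  ok <- tt - half >= min(tt) - TF_TIME_TOL & tt + half <= max(tt) + TF_TIME_TOL
  centers <- tt[ok]
  mp <- vapply(centers, function(tc) {
    inw <- v[tt >= tc - half - TF_TIME_TOL & tt <= tc + half + TF_TIME_TOL]
    mean(inw^p)^(1 / p)
  }, numeric(1))
  structure(data.frame(time_h = centers, m_p = mp),
            p = p, window = window,
            class = c("power_mean_series", "data.frame"))
}

#' Distribution of windowed power-mean speeds across a population
#'
#' Pools, for each time bin, the moving power-mean values of every selected
#' cell whose window centers fall in the bin, and summarizes each bin by a
#' fixed-edge histogram and quartiles. Fixed histogram edges make runs on
#' different datasets directly comparable.
#'
#' @param ds a [tracking_dataset()].
#' @param cell_ids cells to include (default: all with >= 2 track points).
#' @param time_breaks bin edges over recording time, hours.
#' @param p power-mean order.
#' @param window power-mean window width, hours.
#' @param bandwidth smoothing bandwidth, hours.
#' @param speed_breaks histogram edges for the speed axis; default 30 equal
#'   bins over the pooled range.
#' @return list with `bins` (data.frame: `t_lo`, `t_hi`, `count`, `median`,
#'   `q1`, `q3`) and `histogram` (matrix, time bins x speed bins), plus the
#'   edges used.
#' @export
speed_distribution <- function(ds, cell_ids = NULL,
                               time_breaks = seq(0, ds$metadata$duration_h,
                                                 by = 8),
                               p = 1, window = 8, bandwidth = 0.25,
                               speed_breaks = NULL) {
  tr <- ds$tracks
  counts <- table(tr$cell_id)
  if (is.null(cell_ids)) cell_ids <- names(counts)[counts >= 2]
  cell_ids <- intersect(cell_ids, names(counts)[counts >= 2])
  if (length(cell_ids) == 0)
    tf_error("tf_input_error", "no cells with >= 2 track points selected")
  pooled_t <- numeric(0)
  pooled_v <- numeric(0)
  for (id in cell_ids) {
    st <- smooth_trajectory(tr[tr$cell_id == id, , drop = FALSE], bandwidth)
    pm <- moving_power_mean(speed_series(st), p = p, window = window)
    pooled_t <- c(pooled_t, pm$time_h)
    pooled_v <- c(pooled_v, pm$m_p)
  }
  if (is.null(speed_breaks)) {
    hi <- if (length(pooled_v) > 0) max(pooled_v) * 1.0001 else 1
    speed_breaks <- seq(0, hi, length.out = 31)
  }
  bin <- cut(pooled_t, time_breaks, right = FALSE, include.lowest = TRUE)
  nb <- length(time_breaks) - 1
  hist_m <- matrix(0L, nb, length(speed_breaks) - 1)
  bins <- data.frame(t_lo = time_breaks[-length(time_breaks)],
                     t_hi = time_breaks[-1],
                     count = 0L, median = NA_real_, q1 = NA_real_,
                     q3 = NA_real_)
  for (b in seq_len(nb)) {
    v <- pooled_v[!is.na(bin) & as.integer(bin) == b]
    bins$count[b] <- length(v)
    if (length(v) > 0) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      bins$q1[b] <- q[1]; bins$median[b] <- q[2]; bins$q3[b] <- q[3]
      v_in <- v[v >= speed_breaks[1] & v <= speed_breaks[length(speed_breaks)]]
      if (length(v_in) > 0)
        hist_m[b, ] <- tabulate(
          findInterval(v_in, speed_breaks, rightmost.closed = TRUE),
          nbins = length(speed_breaks) - 1)
    }
  }
  list(bins = bins, histogram = hist_m, time_breaks = time_breaks,
       speed_breaks = speed_breaks, p = p, window = window)
}
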