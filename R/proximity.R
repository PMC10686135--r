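# Prolonged cell-cell proximity events: maximal intervals where two
# concurrently-alive cells stay within a distance threshold, excluding a
# window after each cell's birth (sisters are trivially adjacent right
# after division), as a proxy for contact or communication.

#' Detect prolonged proximity events between cell pairs
#'
#' Scans every unordered pair of concurrently-tracked cells on the frame
#' grid and reports the maximal intervals during which their inter-cell
#' (center-to-center) distance stays at or below `threshold`. Frames
#' closer than `birth_exclusion` hours to either cell's birth are ignored,
#' single missing/flickering frames up to `max_gap` hours do not split an
#' event, and only intervals lasting at least `min_duration` hours are
#' reported. Distances are computed on kernel-smoothed positions by
#' default. A bounding-box prefilter skips pairs whose tracks never come
#' within `threshold` of each other; it is exactly equivalent to the
#' brute-force all-pairs scan.
#'
#' @param ds a [tracking_dataset()].
#' @param threshold proximity radius in the dataset's length unit. No
#'   universal value exists; one typical cell diameter of the imaged line
#'   is a reasonable configuration.
#' @param min_duration minimum event duration, hours (default 4).
#' @param birth_exclusion post-birth exclusion window, hours (default 2).
#'   Set `sisters_only_exclusion = TRUE` to apply it only to sister pairs.
#' @param max_gap largest tolerated interruption, hours (default: one
#'   frame interval).
#' @param bandwidth smoothing bandwidth, hours; `smoothing = FALSE` uses
#'   raw positions.
#' @param smoothing logical.
#' @param sisters_only_exclusion see `birth_exclusion`.
#' @return data.frame of class `proximity_events`: `cell_a`, `cell_b`
#'   (sorted within pair), `t_start_h`, `t_end_h`, `min_dist`, `mean_dist`,
#'   `relationship` (`"sisters"`, `"same_tree"`, `"different_trees"`),
#'   ordered by start time then pair ids.
#' @export
detect_proximity_events <- function(ds, threshold,
                                    min_duration = 4,
                                    birth_exclusion = 2,
                                    max_gap = ds$metadata$frame_interval_h,
                                    bandwidth = 0.25,
                                    smoothing = TRUE,
                                    sisters_only_exclusion = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0)
    tf_error("tf_input_error", "distance threshold must be positive")
  cl <- ds$cells
  tr <- ds$tracks
  tr_by_cell <- split(seq_len(nrow(tr)), tr$cell_id)
  ids <- names(tr_by_cell)
  # per-cell positions at its own frame times (smoothed or raw)
  cache <- lapply(ids, function(id) {
    pts <- tr[tr_by_cell[[id]], , drop = FALSE]
    if (nrow(pts) >= 2 && smoothing) {
      p <- predict(smooth_trajectory(pts, bandwidth))
      list(frame = pts$frame, time = pts$time_h, x = p$x, y = p$y,
           birth = cl$birth_time_h[cl$cell_id == id])
    } else {
      list(frame = pts$frame, time = pts$time_h, x = pts$x, y = pts$y,
           birth = cl$birth_time_h[cl$cell_id == id])
    }
  })
  names(cache) <- ids
  root_of <- root_map(cl)
  parent <- stats::setNames(cl$parent_id, cl$cell_id)

  events <- list()
  nid <- length(ids)
  for (a in seq_len(nid - 1L)) for (b in (a + 1L):nid) {
    ca <- cache[[a]]; cb <- cache[[b]]
    common <- intersect(ca$frame, cb$frame)
    if (length(common) == 0) next
    # exact prefilter: tracks whose bounding boxes are farther apart than
    # the threshold in x or y can never produce a near frame
    if (min(ca$x) > max(cb$x) + threshold ||
        min(cb$x) > max(ca$x) + threshold ||
        min(ca$y) > max(cb$y) + threshold ||
        min(cb$y) > max(ca$y) + threshold) next
    ia <- match(common, ca$frame)
    ib <- match(common, cb$frame)
    tt <- ca$time[ia]
    sisters <- !is.na(parent[ids[a]]) && !is.na(parent[ids[b]]) &&
      parent[ids[a]] == parent[ids[b]]
    excl_ok <- if (sisters_only_exclusion && !sisters) rep(TRUE, length(tt))
    else tt >= ca$birth + birth_exclusion - TF_TIME_TOL &
      tt >= cb$birth + birth_exclusion - TF_TIME_TOL
    d <- sqrt((ca$x[ia] - cb$x[ib])^2 + (ca$y[ia] - cb$y[ib])^2)
    near <- d <= threshold & excl_ok
    if (!any(near)) next
    w <- which(near)
    # merge runs of near frames separated by gaps <= max_gap
    brk <- which(diff(tt[w]) > max_gap + TF_TIME_TOL)
    run_start <- c(1L, brk + 1L)
    run_end <- c(brk, length(w))
    for (k in seq_along(run_start)) {
      sel <- w[run_start[k]:run_end[k]]
      dur <- tt[sel[length(sel)]] - tt[sel[1]]
      if (dur + TF_TIME_TOL < min_duration) next
      rel <- if (sisters) "sisters"
      else if (!is.na(root_of[ids[a]]) && !is.na(root_of[ids[b]]) &&
               root_of[ids[a]] == root_of[ids[b]]) "same_tree"
      else "different_trees"
      events[[length(events) + 1L]] <- data.frame(
        cell_a = ids[a], cell_b = ids[b],
        t_start_h = tt[sel[1]], t_end_h = tt[sel[length(sel)]],
        min_dist = min(d[sel]), mean_dist = mean(d[sel]),
        relationship = rel, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(cell_a = character(), cell_b = character(),
               t_start_h = numeric(), t_end_h = numeric(),
               min_dist = numeric(), mean_dist = numeric(),
               relationship = character(), stringsAsFactors = FALSE)
  out <- out[order(out$t_start_h, out$cell_a, out$cell_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold, min_duration = min_duration,
            birth_exclusion = birth_exclusion, max_gap = max_gap,
            class = c("proximity_events", "data.frame"))
}

# map every cell to the root of its tree
root_map <- function(cells) {
  parent <- stats::setNames(cells$parent_id, cells$cell_id)
  vapply(cells$cell_id, function(id) {
    seen <- 0L
    while (!is.na(parent[id])) {
      id <- parent[id]
      seen <- seen + 1L
      if (is.na(match(id, names(parent))) || seen > length(parent))
        return(NA_character_)
    }
    id
  }, character(1))
}

#' Attach proximity events to the trees of a pedigree forest
#'
#' Each event is attached to the tree(s) of its two members: a within-tree
#' event counts once for its tree, a cross-tree event counts once for each
#' of the two trees (so the per-tree cross attachments sum to twice the
#' number of cross-tree events).
#'
#' @param forest a [build_forest()] result.
#' @param events a [detect_proximity_events()] result on the same dataset.
#' @return The forest with an added `events` element: list with `by_tree`
#'   (named list, root -> event row indices) and `summary` (data.frame:
#'   `root`, `n_within`, `n_cross`).
#' @export
annotate_forest <- function(forest, events) {
  cl <- forest$cells
  unknown <- setdiff(unique(c(events$cell_a, events$cell_b)), cl$cell_id)
  if (length(unknown) > 0)
    tf_error("tf_consistency_error",
             "events reference unknown cells: %s",
             paste(unknown, collapse = ", "))
  root_of <- root_map(cl)
  by_tree <- stats::setNames(vector("list", length(forest$trees)),
                             names(forest$trees))
  summ <- data.frame(root = names(forest$trees), n_within = 0L,
                     n_cross = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(events))) {
    ra <- root_of[events$cell_a[i]]
    rb <- root_of[events$cell_b[i]]
    if (ra == rb) {
      by_tree[[ra]] <- c(by_tree[[ra]], i)
      summ$n_within[summ$root == ra] <- summ$n_within[summ$root == ra] + 1L
    } else {
      by_tree[[ra]] <- c(by_tree[[ra]], i)
      by_tree[[rb]] <- c(by_tree[[rb]], i)
      summ$n_cross[summ$root == ra] <- summ$n_cross[summ$root == ra] + 1L
      summ$n_cross[summ$root == rb] <- summ$n_cross[summ$root == rb] + 1L
    }
  }
  forest$events <- list(by_tree = by_tree, summary = summ, table = events)
  forest
}
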