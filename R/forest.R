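# Pedigree forests: lineage topology rooted at the initial (ancestor) cells,
# tree classification by death/survival, and population growth curves with
# their cubic parametrization.

#' Build a pedigree forest from a tracking dataset
#'
#' Groups cells into disjoint trees, one per selected root (a cell with no
#' parent), each containing the root and all of its descendants.
#'
#' @param ds a [tracking_dataset()].
#' @param roots character vector of root cell ids to keep; default all roots.
#' @return An object of class `pedigree_forest`: list with `trees` (named
#'   list, root id -> character vector of member ids, root first, preorder),
#'   `cells` (the lineage records of all members), and the dataset metadata.
#' @export
build_forest <- function(ds, roots = NULL) {
  cl <- ds$cells
  all_roots <- cl$cell_id[is.na(cl$parent_id)]
  if (is.null(roots)) roots <- all_roots
  missing <- setdiff(roots, all_roots)
  if (length(missing) > 0)
    tf_error("tf_lineage_error", "not root cells: %s",
             paste(missing, collapse = ", "))
  kids <- split(cl$cell_id, factor(cl$parent_id, levels = cl$cell_id))
  n_total <- nrow(cl)
  trees <- lapply(roots, function(r) {
    members <- character(0)
    stack <- r
    while (length(stack) > 0) {
      id <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      members <- c(members, id)
      if (length(members) > n_total)
        tf_error("tf_lineage_error", "cycle in parent links near cell %s", id)
      ch <- kids[[id]]
      if (length(ch) > 0) stack <- c(stack, rev(ch))
    }
    members
  })
  names(trees) <- roots
  member_ids <- unlist(trees, use.names = FALSE)
  if (identical(sort(roots), sort(all_roots)) &&
      length(member_ids) < nrow(cl)) {
    stray <- setdiff(cl$cell_id, member_ids)
    tf_error("tf_lineage_error",
             "%d cell(s) unreachable from any root (cycle in parent links?): %s",
             length(stray), paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(trees = trees,
                 cells = cl[match(member_ids, cl$cell_id), , drop = FALSE],
                 metadata = ds$metadata),
            class = "pedigree_forest")
}

#' @export
print.pedigree_forest <- function(x, ...) {
  sizes <- lengths(x$trees)
  cat(sprintf("pedigree_forest: %d trees, %d cells (tree size %d-%d, median %g)\n",
              length(x$trees), sum(sizes), min(sizes), max(sizes),
              stats::median(sizes)))
  invisible(x)
}

#' Select the centered analysis frame containing n root cells
#'
#' Reproduces the study-frame construction used to pick the cohort of
#' founder cells: a rectangle centered at the midpoint of the bounding box
#' of all positions at the start of recording, with the field's aspect
#' ratio, scaled by the smallest factor such that at least `n` root cells
#' lie inside it (boundaries closed). With continuous coordinates ties have
#' probability zero and exactly `n` roots are returned; if several roots are
#' exactly equidistant from the boundary at the minimal scale, all ties are
#' included.
#'
#' @param ds a [tracking_dataset()].
#' @param n target number of root cells in the frame (default 100).
#' @return list with `frame` (named vector `xmin,xmax,ymin,ymax`), `roots`
#'   (ids of contained roots) and `scale` (the minimal scale factor).
#' @export
select_root_frame <- function(ds, n = 100) {
  cl <- ds$cells
  tr <- ds$tracks
  root_ids <- cl$cell_id[is.na(cl$parent_id)]
  t0 <- min(tr$time_h)
  at0 <- tr[tr$time_h == t0, , drop = FALSE]
  if (length(root_ids) < n)
    tf_error("tf_input_error",
             "need at least %d root cells at start of recording, have %d",
             n, length(root_ids))
  # field = bounding box of all positions at the first frame
  cx <- (min(at0$x) + max(at0$x)) / 2
  cy <- (min(at0$y) + max(at0$y)) / 2
  hw <- (max(at0$x) - min(at0$x)) / 2
  hh <- (max(at0$y) - min(at0$y)) / 2
  r0 <- at0[at0$cell_id %in% root_ids, , drop = FALSE]
  # scale at which each root first falls inside the shrinking/growing frame
  sx <- abs(r0$x - cx) / hw
  sy <- abs(r0$y - cy) / hh
  s_in <- pmax(sx, sy)
  s_min <- sort(s_in)[n]
  inside <- s_in <= s_min
  list(frame = c(xmin = cx - s_min * hw, xmax = cx + s_min * hw,
                 ymin = cy - s_min * hh, ymax = cy + s_min * hh),
       roots = r0$cell_id[inside],
       scale = s_min)
}

#' Classify pedigree trees by death and end-of-recording survival
#'
#' A tree is SURVIVING if at least one member is still alive when the
#' recording stops, EXTINCT otherwise; the two classes partition the forest.
#' A surviving tree with no death event among its members is additionally
#' flagged NO_DEATH — the operational proxy for a resistant lineage. Lost
#' cells neither count as deaths nor confer survival.
#'
#' @param forest a [build_forest()] result.
#' @param t_end end of the evaluation window, hours (default: recording
#'   duration).
#' @return data.frame with one row per tree: `root`, `n_members`, `class`
#'   (`"SURVIVING"`/`"EXTINCT"`) and `no_death` (logical).
#' @export
classify_trees <- function(forest, t_end = forest$metadata$duration_h) {
  if (t_end > forest$metadata$duration_h + TF_TIME_TOL)
    tf_error("tf_input_error", "t_end %.6g beyond recording duration %.6g",
             t_end, forest$metadata$duration_h)
  cl <- forest$cells
  idx <- stats::setNames(seq_len(nrow(cl)), cl$cell_id)
  res <- lapply(names(forest$trees), function(r) {
    m <- cl[idx[forest$trees[[r]]], , drop = FALSE]
    surv <- any(m$fate == "ALIVE_AT_END" & m$end_time_h >= t_end - TF_TIME_TOL)
    data.frame(root = r, n_members = nrow(m),
               class = if (surv) "SURVIVING" else "EXTINCT",
               no_death = surv && !any(m$fate %in% DEATH_FATES),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# trees whose members satisfy a subpopulation filter
filter_trees <- function(forest, subpop = c("all", "no_death", "surviving",
                                            "extinct"),
                         t_end = forest$metadata$duration_h) {
  subpop <- match.arg(subpop)
  if (subpop == "all") return(names(forest$trees))
  cls <- classify_trees(forest, t_end)
  switch(subpop,
         no_death = cls$root[cls$no_death],
         surviving = cls$root[cls$class == "SURVIVING"],
         extinct = cls$root[cls$class == "EXTINCT"])
}

#' Population growth curve of a pedigree-tree subpopulation
#'
#' Two normalizations are supported. `"from_start"` counts the cells alive
#' at each grid time across the selected trees, as a percentage of the
#' count at time zero (so the curve starts at 100). `"post_first_division"`
#' aligns each tree at its first cell division and expresses the tree's
#' cell count as a percentage of its single founding cell, then averages
#' the per-tree percentage curves; immediately after the first division a
#' tree has two cells, so every curve — and their average — starts at 200.
#'
#' A cell is counted at time t if `birth <= t < end`; a cell alive at the
#' end of recording is also counted at the final instant. A divided cell is
#' therefore not counted at its division instant while its daughters are.
#'
#' @param forest a [build_forest()] result.
#' @param subpop which trees to include: `"all"`, `"no_death"`,
#'   `"surviving"` or `"extinct"`.
#' @param mode `"from_start"` or `"post_first_division"`.
#' @param step grid step in hours (default: the frame interval).
#' @param t_end evaluation horizon, hours.
#' @return Object of class `growth_curve`: data.frame with `time_h`,
#'   `percent`, `count` (absolute mean count for `post_first_division`,
#'   total count otherwise) and `n_trees` (trees contributing at each grid
#'   time), with attributes `mode` and `subpop`.
#' @export
population_growth_curve <- function(forest,
                                    subpop = "all",
                                    mode = c("from_start",
                                             "post_first_division"),
                                    step = forest$metadata$frame_interval_h,
                                    t_end = forest$metadata$duration_h) {
  mode <- match.arg(mode)
  roots <- filter_trees(forest, subpop, t_end)
  if (length(roots) == 0)
    tf_error("tf_input_error", "no trees in subpopulation '%s'", subpop)
  cl <- forest$cells
  idx <- stats::setNames(seq_len(nrow(cl)), cl$cell_id)

  if (mode == "from_start") {
    grid <- seq(0, t_end, by = step)
    members <- cl[idx[unlist(forest$trees[roots], use.names = FALSE)], ,
                  drop = FALSE]
    counts <- vapply(grid, function(t) sum(alive_at(members, t)), numeric(1))
    if (counts[1] == 0)
      tf_error("tf_input_error", "no cells alive at time 0")
    out <- data.frame(time_h = grid, percent = 100 * counts / counts[1],
                      count = counts, n_trees = length(roots))
  } else {
    # first division of a tree is its root's division
    div_time <- vapply(roots, function(r) {
      m <- cl[idx[forest$trees[[r]]], , drop = FALSE]
      dv <- m$end_time_h[m$fate == "DIVIDED"]
      if (length(dv) == 0) NA_real_ else min(dv)
    }, numeric(1))
    roots <- roots[!is.na(div_time)]
    div_time <- div_time[!is.na(div_time)]
    if (length(roots) == 0)
      tf_error("tf_input_error",
               "no dividing trees in subpopulation for post_first_division")
    grid <- seq(0, t_end - min(div_time), by = step)
    per_tree <- vapply(seq_along(roots), function(k) {
      m <- cl[idx[forest$trees[[roots[k]]]], , drop = FALSE]
      tt <- div_time[k] + grid
      n <- vapply(tt, function(t) sum(alive_at(m, t)), numeric(1))
      n[tt > t_end + TF_TIME_TOL] <- NA_real_
      n
    }, numeric(length(grid)))
    per_tree <- matrix(per_tree, nrow = length(grid))
    n_trees <- rowSums(!is.na(per_tree))
    mean_count <- rowMeans(per_tree, na.rm = TRUE)
    keep <- n_trees > 0
    out <- data.frame(time_h = grid[keep],
                      percent = 100 * mean_count[keep],
                      count = mean_count[keep], n_trees = n_trees[keep])
  }
  rownames(out) <- NULL
  structure(out, mode = mode, subpop = subpop,
            class = c("growth_curve", "data.frame"))
}

#' Fit the fixed-intercept cubic growth model
#'
#' Fits the three-parameter polynomial P3(t) = 100 + a t + b t^2 + c t^3 to
#' a percentage growth curve by least squares. The intercept is not a free
#' parameter: the curve is normalized to 100 at time zero, so the fit
#' regresses `percent - 100` on the basis `{t, t^2, t^3}` with no constant
#' term, and `P3(0) = 100` holds exactly. The triple (a, b, c) is the
#' compressed representation of the curve.
#'
#' @param curve a `growth_curve` in `"from_start"` mode (or any data.frame
#'   with `time_h` and `percent`), at least 4 grid points.
#' @return Object of class `growth_fit`: list with `coefficients` (named
#'   `a` (%/h), `b` (%/h^2), `c` (%/h^3)), `rss`, `fitted`, `residuals`,
#'   `curve`.
#' @export
fit_growth_polynomial <- function(curve) {
  md <- attr(curve, "mode")
  if (!is.null(md) && md != "from_start")
    tf_error("tf_input_error",
             "growth fit is defined for 'from_start' curves, got '%s'", md)
  t <- curve$time_h
  y <- curve$percent - 100
  if (length(t) < 4)
    tf_error("tf_input_error", "need at least 4 grid points, have %d",
             length(t))
  X <- cbind(t = t, t2 = t^2, t3 = t^3)
  if (qr(X)$rank < 3)
    tf_error("tf_input_error", "degenerate time grid: basis {t,t^2,t^3} is rank-deficient")
  fit <- stats::lm.fit(X, y)
  cf <- stats::setNames(fit$coefficients, c("a", "b", "c"))
  structure(list(coefficients = cf,
                 rss = sum(fit$residuals^2),
                 fitted = 100 + X %*% cf,
                 residuals = fit$residuals,
                 curve = curve),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 6, ...) {
  cat("Cubic growth model  P3(t) = 100 + a t + b t^2 + c t^3\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("RSS %.6g on %d grid points\n", x$rss, length(x$residuals)))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$curve$time_h else newdata
  cf <- object$coefficients
  drop(100 + cf["a"] * t + cf["b"] * t^2 + cf["c"] * t^3)
}

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' Export a growth curve or fit
#'
#' Growth curves are written as CSV (`time_h,percent`); fits as JSON with
#' the coefficient triple, the residual sum of squares and provenance
#' labels.
#'
#' @param x a `growth_curve` or `growth_fit`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
export_growth <- function(x, path) {
  if (inherits(x, "growth_fit")) {
    jsonlite::write_json(
      list(a = unname(x$coefficients["a"]), b = unname(x$coefficients["b"]),
           c = unname(x$coefficients["c"]), rss = x$rss,
           mode = attr(x$curve, "mode"), subpop = attr(x$curve, "subpop")),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(x)[, c("time_h", "percent")], path,
                     row.names = FALSE)
  }
  invisible(path)
}
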