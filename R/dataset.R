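# On-disk and in-memory representation of single-cell tracking datasets.
#
# A dataset is two tables: per-frame positions ("tracks") and per-cell
# lineage records ("cells"), plus recording metadata. The canonical on-disk
# form is a pair of UTF-8 comma-separated files with '.' decimal separator
# and fixed headers; an empty parent_id marks a root cell.

#' Terminal fates a tracked cell can take
#'
#' A cell's track ends in exactly one of five ways: it divides into two
#' daughters, it dies with apoptosis-like or necrosis-like morphology, it is
#' still alive when the recording stops, or it is lost to tracking (leaves
#' the field of view or the tracker fails).
#'
#' @format Character vector of the five admitted fate labels.
#' @export
CELL_FATES <- c("DIVIDED", "DEATH_APOPTOTIC", "DEATH_NECROTIC",
                "ALIVE_AT_END", "LOST")

DEATH_FATES <- c("DEATH_APOPTOTIC", "DEATH_NECROTIC")

TRACK_HEADER <- c("cell_id", "frame", "time_h", "x", "y")
CELL_HEADER <- c("cell_id", "parent_id", "birth_time_h", "end_time_h", "fate")

tf_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Construct a tracking dataset
#'
#' Bundles a per-frame position table, a per-cell lineage table and
#' recording metadata into a `tracking_dataset`. The object is the input of
#' every analysis in the package.
#'
#' @param tracks data.frame with columns `cell_id` (character), `frame`
#'   (non-negative integer), `time_h` (hours since start of recording),
#'   `x`, `y` (positions in the spatial unit recorded in `metadata`).
#' @param cells data.frame with columns `cell_id`, `parent_id` (character,
#'   `NA` for root cells), `birth_time_h`, `end_time_h`, `fate` (one of
#'   [CELL_FATES]).
#' @param frame_interval_h time between consecutive frames, hours.
#' @param duration_h total recording duration, hours.
#' @param exposure free-text label of the treatment/exposure.
#' @param spatial_unit unit of `x`/`y`; statistics are unit-agnostic.
#' @param check if `TRUE` (default), stop on the first invariant violation.
#' @return An object of class `tracking_dataset`: a list with elements
#'   `tracks`, `cells` and `metadata`.
#' @seealso [read_dataset()], [write_dataset()], [validate_dataset()]
#' @export
tracking_dataset <- function(tracks, cells,
                             frame_interval_h = 0.1,
                             duration_h = 94,
                             exposure = "",
                             spatial_unit = "um",
                             check = TRUE) {
  tracks <- as.data.frame(tracks, stringsAsFactors = FALSE)
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (!identical(names(tracks), TRACK_HEADER))
    tf_error("tf_format_error", "track table must have columns %s",
             paste(TRACK_HEADER, collapse = ","))
  if (!identical(names(cells), CELL_HEADER))
    tf_error("tf_format_error", "cell table must have columns %s",
             paste(CELL_HEADER, collapse = ","))
  tracks$cell_id <- as.character(tracks$cell_id)
  tracks$frame <- as.integer(tracks$frame)
  cells$cell_id <- as.character(cells$cell_id)
  cells$parent_id <- as.character(cells$parent_id)
  cells$parent_id[!is.na(cells$parent_id) & cells$parent_id == ""] <- NA_character_
  rownames(tracks) <- NULL
  rownames(cells) <- NULL
  ds <- structure(
    list(tracks = tracks, cells = cells,
         metadata = list(frame_interval_h = frame_interval_h,
                         duration_h = duration_h,
                         exposure = exposure,
                         spatial_unit = spatial_unit)),
    class = "tracking_dataset")
  if (check) {
    rep <- validate_dataset(ds)
    if (nrow(rep) > 0) {
      v <- rep[1L, ]
      cls <- switch(v$rule,
                    orphan_parent = ,
                    missing_children = ,
                    child_birth_mismatch = "tf_lineage_error",
                    track_order = "tf_order_error",
                    "tf_format_error")
      tf_error(cls, "invalid dataset (%d violation%s); first: [%s] cell %s: %s",
               nrow(rep), if (nrow(rep) > 1) "s" else "",
               v$rule, v$cell_id, v$message)
    }
  }
  ds
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat(sprintf("tracking_dataset: %d cells, %d track points\n",
              nrow(x$cells), nrow(x$tracks)))
  cat(sprintf("  recording: %.3g h at %.3g h/frame, exposure '%s', unit %s\n",
              x$metadata$duration_h, x$metadata$frame_interval_h,
              x$metadata$exposure, x$metadata$spatial_unit))
  n_root <- sum(is.na(x$cells$parent_id))
  cat(sprintf("  roots: %d; fates: %s\n", n_root,
              paste(sprintf("%s=%d", names(table(x$cells$fate)),
                            as.integer(table(x$cells$fate))), collapse = " ")))
  invisible(x)
}

#' Read a tracking dataset from its canonical CSV pair
#'
#' Reads the two comma-separated files produced by [write_dataset()] (or any
#' tracker exporting the same dialect), checks every structural invariant,
#' and returns a validated [tracking_dataset()].
#'
#' @param track_path path to the per-frame position CSV
#'   (`cell_id,frame,time_h,x,y`).
#' @param cell_path path to the per-cell lineage CSV
#'   (`cell_id,parent_id,birth_time_h,end_time_h,fate`).
#' @inheritParams tracking_dataset
#' @return A validated `tracking_dataset`.
#' @details Errors are classed: malformed headers raise a format error,
#'   an absent parent a lineage error, non-monotone frame times an ordering
#'   error; messages name the offending cell.
#' @export
read_dataset <- function(track_path, cell_path,
                         frame_interval_h = 0.1, duration_h = 94,
                         exposure = "", spatial_unit = "um") {
  for (p in c(track_path, cell_path))
    if (!file.exists(p)) tf_error("tf_format_error", "file not found: %s", p)
  tr_head <- names(utils::read.csv(track_path, nrows = 0))
  if (!identical(tr_head, TRACK_HEADER))
    tf_error("tf_format_error",
             "bad track header in %s: got '%s'", track_path,
             paste(tr_head, collapse = ","))
  cl_head <- names(utils::read.csv(cell_path, nrows = 0))
  if (!identical(cl_head, CELL_HEADER))
    tf_error("tf_format_error",
             "bad cell header in %s: got '%s'", cell_path,
             paste(cl_head, collapse = ","))
  tracks <- utils::read.csv(track_path, colClasses = c(
    cell_id = "character", frame = "integer", time_h = "numeric",
    x = "numeric", y = "numeric"))
  cells <- utils::read.csv(cell_path, colClasses = c(
    cell_id = "character", parent_id = "character",
    birth_time_h = "numeric", end_time_h = "numeric", fate = "character"),
    na.strings = "")
  tracking_dataset(tracks, cells,
                   frame_interval_h = frame_interval_h,
                   duration_h = duration_h,
                   exposure = exposure, spatial_unit = spatial_unit)
}

#' Write a tracking dataset to its canonical CSV pair
#'
#' Inverse of [read_dataset()]: values round-trip exactly for identifiers,
#' frames and fates, and to at least 9 significant digits for times and
#' coordinates.
#'
#' @param ds a [tracking_dataset()].
#' @param track_path,cell_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(ds, track_path, cell_path) {
  stopifnot(inherits(ds, "tracking_dataset"))
  utils::write.csv(ds$tracks, track_path, row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(ds$cells, cell_path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(c(track_path, cell_path))
}

# numeric tolerance used when comparing event times that should coincide
TF_TIME_TOL <- 1e-9

#' Validate a tracking dataset
#'
#' Checks every structural invariant of the data model and returns the full
#' list of violations as data — an empty report means a valid dataset.
#' Unlike [read_dataset()], nothing is thrown.
#'
#' Rules checked, in report order per cell: fate labels admitted
#' (`bad_fate`), birth strictly before end (`birth_end_order`),
#' daughter birth times equal to the mother's division time
#' (`child_birth_mismatch`), coordinates finite (`coords_finite`),
#' cells present in both tables (`missing_in_cells`, `missing_in_tracks`),
#' two children per divided cell (`missing_children`), parents present
#' (`orphan_parent`), frames/times strictly increasing and non-negative
#' (`track_order`, `negative_time`), and track points inside the cell's
#' lifespan (`track_outside_lifespan`).
#'
#' @param ds a `tracking_dataset` (possibly built with `check = FALSE`).
#' @return data.frame with columns `cell_id`, `rule`, `message`, ordered by
#'   `cell_id` then `rule`.
#' @export
validate_dataset <- function(ds) {
  tr <- ds$tracks
  cl <- ds$cells
  out <- list()
  add <- function(cell_id, rule, message)
    out[[length(out) + 1L]] <<- data.frame(
      cell_id = cell_id, rule = rule, message = message,
      stringsAsFactors = FALSE)

  dup <- cl$cell_id[duplicated(cl$cell_id)]
  for (id in unique(dup)) add(id, "duplicate_cell", "duplicate cell_id in cell table")

  bad <- !(cl$fate %in% CELL_FATES)
  for (i in which(bad)) add(cl$cell_id[i], "bad_fate",
                            sprintf("unknown fate '%s'", cl$fate[i]))

  rev_life <- cl$birth_time_h >= cl$end_time_h
  for (i in which(rev_life)) add(cl$cell_id[i], "birth_end_order",
                                 sprintf("birth %.6g not before end %.6g",
                                         cl$birth_time_h[i], cl$end_time_h[i]))

  known <- cl$cell_id
  orphan <- !is.na(cl$parent_id) & !(cl$parent_id %in% known)
  for (i in which(orphan)) add(cl$cell_id[i], "orphan_parent",
                               sprintf("parent '%s' not in cell table",
                                       cl$parent_id[i]))

  # division topology: exactly two children, born at the mother's end time
  kid_of <- split(seq_len(nrow(cl)), cl$parent_id)
  for (i in which(cl$fate == "DIVIDED")) {
    kids <- kid_of[[cl$cell_id[i]]]
    nk <- length(kids)
    if (nk != 2L) {
      add(cl$cell_id[i], "missing_children",
          sprintf("DIVIDED cell has %d child(ren), expected 2", nk))
    } else {
      off <- abs(cl$birth_time_h[kids] - cl$end_time_h[i]) > TF_TIME_TOL
      for (k in kids[off])
        add(cl$cell_id[k], "child_birth_mismatch",
            sprintf("birth %.9g != mother '%s' division at %.9g",
                    cl$birth_time_h[k], cl$cell_id[i], cl$end_time_h[i]))
    }
  }
  # non-divided cells must have no children
  for (i in which(cl$fate != "DIVIDED")) {
    kids <- kid_of[[cl$cell_id[i]]]
    if (length(kids) > 0L)
      add(cl$cell_id[i], "missing_children",
          sprintf("non-divided cell has %d child(ren)", length(kids)))
  }

  only_tr <- setdiff(unique(tr$cell_id), known)
  for (id in only_tr) add(id, "missing_in_cells",
                          "cell has track points but no lineage record")
  only_cl <- setdiff(known, unique(tr$cell_id))
  for (id in only_cl) add(id, "missing_in_tracks",
                          "cell has a lineage record but no track points")

  bad_coord <- !is.finite(tr$x) | !is.finite(tr$y)
  for (id in unique(tr$cell_id[bad_coord]))
    add(id, "coords_finite", "non-finite coordinate")
  neg_t <- is.finite(tr$time_h) & tr$time_h < 0
  for (id in unique(tr$cell_id[neg_t])) add(id, "negative_time",
                                            "track time before start of recording")

  idx_by_cell <- split(seq_len(nrow(tr)), tr$cell_id)
  life <- stats::setNames(seq_len(nrow(cl)), cl$cell_id)
  for (id in names(idx_by_cell)) {
    ii <- idx_by_cell[[id]]
    if (length(ii) > 1L) {
      if (any(diff(tr$frame[ii]) <= 0L) || any(diff(tr$time_h[ii]) <= 0))
        add(id, "track_order", "frames/times not strictly increasing")
    }
    j <- life[id]
    if (!is.na(j)) {
      lo <- cl$birth_time_h[j] - TF_TIME_TOL
      hi <- cl$end_time_h[j] + TF_TIME_TOL
      if (any(tr$time_h[ii] < lo | tr$time_h[ii] > hi))
        add(id, "track_outside_lifespan",
            "track point outside [birth_time_h, end_time_h]")
    }
  }

  if (length(out) == 0L)
    return(data.frame(cell_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  rep <- do.call(rbind, out)
  rep <- rep[order(rep$cell_id, rep$rule), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

# cells alive at time t under the half-open lifespan convention:
# birth <= t < end, except cells alive at the end of recording which are
# also counted at t == end (the recording boundary is not an event).
alive_at <- function(cells, t) {
  (cells$birth_time_h <= t & t < cells$end_time_h) |
    (cells$fate == "ALIVE_AT_END" & cells$birth_time_h <= t &
       t <= cells$end_time_h)
}
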