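#' @title Per-second activity data model for VMR assays
#'
#' @description
#' The central data structure of the package is the activity matrix: one row
#' per animal and per second of the assay, holding the Burst Duration (the
#' fraction of video frames within that second in which the animal was
#' detected moving, a unitless value in [0, 1]) together with per-animal
#' factor metadata (strain, developmental stage in dpf, well position,
#' biological repeat, plate).
#'
#' The second-indexing convention is fixed throughout the package: second
#' \code{s} summarizes frames falling in the half-open interval
#' \code{[s - 1, s)} seconds, so the value recorded at second 1 covers
#' activity between time 0 and time 1.
#'
#' @name activity-model
NULL

ACTIVITY_COLS <- c("animal_id", "strain", "stage_dpf", "well", "bio_rep",
                   "plate_id", "second", "activity")
META_COLS <- c("strain", "stage_dpf", "well", "bio_rep", "plate_id")

#' Construct and validate an activity matrix
#'
#' @param df data.frame with columns \code{animal_id}, \code{second} (integer,
#'   1-based absolute experiment time), \code{activity} (Burst Duration in
#'   [0, 1]) and the metadata columns \code{strain}, \code{stage_dpf},
#'   \code{well}, \code{bio_rep}, \code{plate_id}. Missing metadata columns
#'   are filled with \code{NA}.
#' @return the validated data.frame with class \code{vmr_activity}.
#' @export
activity_matrix <- function(df) {
  if (!is.data.frame(df)) vmr_abort("activity matrix input must be a data.frame", "vmr_schema_error")
  need <- c("animal_id", "second", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    vmr_abort(paste0("activity table is missing required column(s): ",
                     paste(miss, collapse = ", ")), "vmr_schema_error")
  }
  for (m in META_COLS) if (!m %in% names(df)) df[[m]] <- NA
  df <- as.data.frame(df)[, ACTIVITY_COLS]
  bad <- which(!is.finite(df$activity) | df$activity < 0 | df$activity > 1)
  if (length(bad) > 0) {
    vmr_abort(sprintf("activity outside [0,1] at row(s) %s (first bad value %.6g)",
                      paste(utils::head(bad, 5), collapse = ", "), df$activity[bad[1]]),
              "vmr_validation_error")
  }
  if (any(df$second != round(df$second))) {
    vmr_abort("second must be integer-valued", "vmr_validation_error")
  }
  df$second <- as.integer(df$second)
  if (anyDuplicated(df[, c("animal_id", "second")]) > 0) {
    vmr_abort("duplicate (animal_id, second) rows in activity table", "vmr_validation_error")
  }
  class(df) <- c("vmr_activity", "data.frame")
  df
}

#' Construct and validate a frame-level movement table
#'
#' One row per animal and video frame with a binary moved/not-moved call.
#' Pixel-level detection is upstream of this package; the table holds its
#' per-frame output.
#'
#' @param df data.frame with columns \code{animal_id}, \code{frame_index}
#'   (0-based, absolute) and \code{moved} (0/1).
#' @param fps frames per second of the recording (positive integer).
#' @return data.frame of class \code{vmr_frames} with attribute \code{fps}.
#' @export
frame_table <- function(df, fps = 30) {
  if (!is_count(fps)) vmr_abort("fps must be a positive integer", "vmr_validation_error")
  miss <- setdiff(c("animal_id", "frame_index", "moved"), names(df))
  if (length(miss) > 0) {
    vmr_abort(paste0("frame table is missing required column(s): ",
                     paste(miss, collapse = ", ")), "vmr_schema_error")
  }
  if (!all(df$moved %in% c(0, 1))) {
    vmr_abort("moved flag must be 0 or 1 for every frame", "vmr_malformed_input")
  }
  if (any(df$frame_index < 0 | df$frame_index != round(df$frame_index))) {
    vmr_abort("frame_index must be a non-negative integer", "vmr_malformed_input")
  }
  if (anyDuplicated(df[, c("animal_id", "frame_index")]) > 0) {
    vmr_abort("duplicate (animal_id, frame_index) rows in frame table", "vmr_malformed_input")
  }
  df <- as.data.frame(df)[, c("animal_id", "frame_index", "moved")]
  df$frame_index <- as.integer(df$frame_index)
  df$moved <- as.integer(df$moved)
  attr(df, "fps") <- as.integer(fps)
  class(df) <- c("vmr_frames", "data.frame")
  df
}

#' Construct and validate a stimulus schedule
#'
#' Light-change events of the assay: the absolute second of each transition,
#' whether light switched On or Off, and the trial (technical repeat) index.
#' Transitions must strictly increase in time and alternate On/Off; event
#' times must fall on integer second boundaries (light changes in this assay
#' are abrupt, not fading, so sub-second events are rejected rather than
#' interpolated).
#'
#' @param df data.frame with columns \code{event_time_s}, \code{transition}
#'   (\code{"on"}/\code{"off"}, case-insensitive), \code{trial_index}.
#' @return data.frame of class \code{vmr_schedule}.
#' @export
stimulus_schedule <- function(df) {
  miss <- setdiff(c("event_time_s", "transition", "trial_index"), names(df))
  if (length(miss) > 0) {
    vmr_abort(paste0("schedule is missing required column(s): ",
                     paste(miss, collapse = ", ")), "vmr_schema_error")
  }
  df <- as.data.frame(df)[, c("event_time_s", "transition", "trial_index")]
  df$transition <- tolower(as.character(df$transition))
  if (!all(df$transition %in% c("on", "off"))) {
    vmr_abort("transition must be 'on' or 'off'", "vmr_schema_error")
  }
  if (any(df$event_time_s != round(df$event_time_s))) {
    vmr_abort("event times must fall on integer second boundaries", "vmr_schema_error")
  }
  df$event_time_s <- as.integer(df$event_time_s)
  df$trial_index <- as.integer(df$trial_index)
  if (nrow(df) > 1) {
    if (any(diff(df$event_time_s) <= 0)) {
      vmr_abort("event times must be strictly increasing", "vmr_schema_error")
    }
    if (any(df$transition[-1] == df$transition[-nrow(df)])) {
      vmr_abort("transitions must alternate on/off within the schedule", "vmr_schema_error")
    }
  }
  class(df) <- c("vmr_schedule", "data.frame")
  df
}

#' Summarize frame-level movement into per-second Burst Duration
#'
#' For each animal and each fully covered second \code{s}, the Burst Duration
#' is the number of frames with \code{moved = 1} among the \code{fps} frames
#' in \code{[s - 1, s)} seconds, divided by \code{fps}. A trailing second for
#' which fewer than \code{fps} frames were recorded is dropped.
#'
#' An optional burst-threshold filter is available for compatibility with
#' acquisition systems that discard small movements: frames are counted as
#' moved only when \code{moved = 1}; the filter is applied upstream of this
#' function by the acquisition software and defaults to off here.
#'
#' @param frames a \code{\link{frame_table}}.
#' @param metadata optional data.frame keyed by \code{animal_id} carrying the
#'   per-animal factor columns (\code{strain}, \code{stage_dpf}, \code{well},
#'   \code{bio_rep}, \code{plate_id}); joined onto the output.
#' @return a \code{\link{activity_matrix}}.
#' @export
summarize_burst_duration <- function(frames, metadata = NULL) {
  if (!inherits(frames, "vmr_frames")) frames <- frame_table(frames)
  fps <- attr(frames, "fps")
  # frame f (0-based) lies in second floor(f / fps) + 1
  sec <- frames$frame_index %/% fps + 1L
  agg <- stats::aggregate(
    cbind(moved_n = frames$moved, frame_n = rep(1L, nrow(frames))),
    by = list(animal_id = frames$animal_id, second = sec), FUN = sum)
  agg <- agg[agg$frame_n == fps, , drop = FALSE]  # drop partial trailing seconds
  out <- data.frame(animal_id = agg$animal_id,
                    second = agg$second,
                    activity = agg$moved_n / fps)
  if (!is.null(metadata)) {
    out <- merge(out, metadata[, c("animal_id", intersect(META_COLS, names(metadata)))],
                 by = "animal_id", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(out$animal_id, out$second), ]
  rownames(out) <- NULL
  activity_matrix(out)
}

#' Extract fixed-length activity windows around light-change events
#'
#' For every animal and every scheduled event at absolute second \code{E},
#' the pre-change vector covers absolute seconds \code{E - pre_len + 1 .. E}
#' (relative seconds \code{-pre_len + 1 .. 0}; relative second 0 is the last
#' pre-change second) and the post-change vector covers
#' \code{E + 1 .. E + post_len} (relative seconds \code{1 .. post_len}).
#' Animals missing any second of a window are excluded from that event only
#' (complete-case per animal-by-event); the exclusion count is recorded in
#' the result and reported via a message.
#'
#' @param activity an \code{\link{activity_matrix}}.
#' @param schedule a \code{\link{stimulus_schedule}}.
#' @param pre_len,post_len window lengths in seconds (default 30 and 30).
#' @return an object of class \code{vmr_windows}: a list with \code{values}
#'   (one row per retained animal-by-event, one column per relative second),
#'   \code{meta} (stimulus, trial index, event time and the animal metadata),
#'   \code{rel_seconds}, \code{pre_len}, \code{post_len}, \code{n_excluded}.
#' @export
extract_windows <- function(activity, schedule, pre_len = 30, post_len = 30) {
  if (!inherits(activity, "vmr_activity")) activity <- activity_matrix(activity)
  if (!inherits(schedule, "vmr_schedule")) schedule <- stimulus_schedule(schedule)
  if (!is_count(pre_len) || !is_count(post_len)) {
    vmr_abort("pre_len and post_len must be positive integers", "vmr_validation_error")
  }
  sec_range <- range(activity$second)
  for (i in seq_len(nrow(schedule))) {
    E <- schedule$event_time_s[i]
    if (E - pre_len + 1 < sec_range[1] || E + post_len > sec_range[2]) {
      vmr_abort(sprintf(
        "event at second %d (%s, trial %d) needs seconds %d..%d but recording covers %d..%d",
        E, schedule$transition[i], schedule$trial_index[i],
        E - pre_len + 1, E + post_len, sec_range[1], sec_range[2]),
        "vmr_window_out_of_range")
    }
  }
  rel_seconds <- c(seq.int(-pre_len + 1L, 0L), seq.int(1L, post_len))
  animals <- sort(unique(activity$animal_id))
  # sparse lookup restricted to the seconds any window touches
  needed <- sort(unique(as.vector(outer(schedule$event_time_s, rel_seconds, "+"))))
  sec_idx <- match(activity$second, needed)
  rel_rows <- which(!is.na(sec_idx))
  M <- matrix(NA_real_, length(animals), length(needed))
  M[cbind(match(activity$animal_id[rel_rows], animals), sec_idx[rel_rows])] <-
    activity$activity[rel_rows]
  meta_per_animal <- activity[!duplicated(activity$animal_id),
                              c("animal_id", META_COLS), drop = FALSE]
  vals <- list(); keeps <- list(); n_excluded <- 0L
  for (i in seq_len(nrow(schedule))) {
    cols <- match(schedule$event_time_s[i] + rel_seconds, needed)
    W <- M[, cols, drop = FALSE]
    complete <- rowSums(is.na(W)) == 0L
    n_excluded <- n_excluded + sum(!complete)
    vals[[i]] <- W[complete, , drop = FALSE]
    keeps[[i]] <- which(complete)
  }
  if (sum(vapply(vals, nrow, integer(1))) == 0) {
    vmr_abort("no complete animal-by-event windows", "vmr_validation_error")
  }
  values <- do.call(rbind, vals)
  colnames(values) <- as.character(rel_seconds)
  n_per_event <- vapply(keeps, length, integer(1))
  meta <- data.frame(
    animal_id = animals[unlist(keeps)],
    stimulus = rep(schedule$transition, n_per_event),
    trial_index = rep(schedule$trial_index, n_per_event),
    event_time_s = rep(schedule$event_time_s, n_per_event))
  meta <- cbind(meta, meta_per_animal[match(meta$animal_id, meta_per_animal$animal_id),
                                      META_COLS, drop = FALSE])
  rownames(meta) <- NULL
  if (n_excluded > 0) {
    message(sprintf("extract_windows: excluded %d incomplete animal-by-event window(s)",
                    n_excluded))
  }
  structure(list(values = values, meta = meta, rel_seconds = rel_seconds,
                 pre_len = as.integer(pre_len), post_len = as.integer(post_len),
                 n_excluded = n_excluded),
            class = "vmr_windows")
}

#' @export
print.vmr_windows <- function(x, ...) {
  cat(sprintf("VMR windowed activity set: %d animal-by-event rows, rel seconds %d..%d\n",
              nrow(x$values), min(x$rel_seconds), max(x$rel_seconds)))
  cat(sprintf("  stimuli: %s; trials: %s; excluded incomplete windows: %d\n",
              paste(unique(x$meta$stimulus), collapse = "/"),
              paste(sort(unique(x$meta$trial_index)), collapse = ","),
              x$n_excluded))
  invisible(x)
}

# Resolve a window tag to column indices of the values matrix.
# Tags: "pre" (-pre_len+1..0), "post" (1..post_len), "full", or an integer
# vector c(a, b) of relative seconds.
window_columns <- function(windows, window) {
  rs <- windows$rel_seconds
  if (is.character(window)) {
    window <- match.arg(window, c("pre", "post", "full"))
    sel <- switch(window, pre = rs <= 0, post = rs >= 1, full = rep(TRUE, length(rs)))
    return(which(sel))
  }
  if (is.numeric(window) && length(window) == 2) {
    sel <- which(rs >= window[1] & rs <= window[2])
    if (length(sel) != window[2] - window[1] + 1) {
      vmr_abort(sprintf("relative seconds %d..%d not fully covered by the windows",
                        window[1], window[2]), "vmr_validation_error")
    }
    return(sel)
  }
  vmr_abort("window must be 'pre', 'post', 'full' or c(from, to) relative seconds",
            "vmr_validation_error")
}

#' Extract the activity matrix of a window interval
#'
#' @param windows a \code{vmr_windows} object.
#' @param window \code{"pre"}, \code{"post"}, \code{"full"} or
#'   \code{c(from, to)} in relative seconds.
#' @param subset optional logical vector over rows of the windowed set.
#' @return numeric matrix, rows = animal-by-event observations, columns =
#'   relative seconds.
#' @export
window_matrix <- function(windows, window = "post", subset = NULL) {
  cols <- window_columns(windows, window)
  v <- windows$values[, cols, drop = FALSE]
  if (!is.null(subset)) v <- v[subset, , drop = FALSE]
  v
}

#' Mean/SD activity traces by group
#'
#' Per group (defined by metadata fields) and relative second: arithmetic
#' mean, sample standard deviation (divisor n - 1; reported as 0 when n = 1),
#' and the number of animal-by-event observations. Trials pooled within a
#' group are averaged together.
#'
#' @param windows a \code{vmr_windows} object.
#' @param grouping character vector of metadata fields (e.g.
#'   \code{c("strain", "stimulus")}).
#' @return long-form data.frame: grouping columns, \code{rel_second},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
summarize_traces <- function(windows, grouping = c("strain", "stimulus")) {
  miss <- setdiff(grouping, names(windows$meta))
  if (length(miss) > 0) {
    vmr_abort(paste0("grouping field(s) not in metadata: ", paste(miss, collapse = ", ")),
              "vmr_schema_error")
  }
  key <- interaction(windows$meta[, grouping, drop = FALSE], drop = TRUE, sep = "\r")
  out <- list()
  for (lev in levels(key)) {
    idx <- which(key == lev)
    if (length(idx) == 0) { vmr_warn(sprintf("empty group '%s' omitted", lev)); next }
    v <- windows$values[idx, , drop = FALSE]
    mu <- colMeans(v)
    sdv <- if (length(idx) == 1) rep(0, ncol(v)) else apply(v, 2, stats::sd)
    gvals <- strsplit(lev, "\r", fixed = TRUE)[[1]]
    g <- as.data.frame(as.list(gvals), col.names = grouping, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- cbind(g[rep(1, length(mu)), , drop = FALSE],
                                     data.frame(rel_second = windows$rel_seconds,
                                                mean = mu, sd = sdv, n = length(idx)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
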