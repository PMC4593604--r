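# Readers/writers. One dialect everywhere: comma-delimited, UTF-8, '.'
# decimal, header row required. Round trips are bit-exact for
# text-representable floats (values written with full precision via
# format(..., digits = 17)).

read_csv_strict <- function(path, required, what) {
  if (!file.exists(path)) {
    vmr_abort(paste0(what, " file not found: ", path), "vmr_io_error")
  }
  df <- utils::read.csv(path, header = TRUE, comment.char = "#",
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    vmr_abort(paste0(what, " file ", path, " is missing column(s): ",
                     paste(miss, collapse = ", ")), "vmr_schema_error")
  }
  df
}

write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

#' Read / write activity tables
#'
#' Columns: \code{animal_id, strain, stage_dpf, well, bio_rep, plate_id,
#' second, activity}.
#'
#' @param path file path (CSV, header required).
#' @return \code{read_activity_table}: a validated
#'   \code{\link{activity_matrix}}.
#' @export
read_activity_table <- function(path) {
  activity_matrix(read_csv_strict(path, ACTIVITY_COLS, "activity table"))
}

#' @rdname read_activity_table
#' @param activity an \code{\link{activity_matrix}}.
#' @export
write_activity_table <- function(activity, path) {
  if (!inherits(activity, "vmr_activity")) activity <- activity_matrix(activity)
  write_csv_full(as.data.frame(activity), path)
  invisible(path)
}

#' Read / write frame-level movement tables
#'
#' Columns: \code{animal_id, frame_index, moved}. The frame rate is taken
#' from a \code{# fps=N} comment line at the top of the file; the \code{fps}
#' argument overrides it.
#'
#' @param path file path.
#' @param fps frames per second; overrides any header comment.
#' @export
read_frame_table <- function(path, fps = NULL) {
  if (is.null(fps)) {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec("^#\\s*fps\\s*=\\s*([0-9]+)", first))[[1]]
    fps <- if (length(m) == 2) as.integer(m[2]) else 30L
  }
  frame_table(read_csv_strict(path, c("animal_id", "frame_index", "moved"),
                              "frame table"), fps = fps)
}

#' @rdname read_frame_table
#' @param frames a \code{\link{frame_table}}.
#' @export
write_frame_table <- function(frames, path) {
  if (!inherits(frames, "vmr_frames")) frames <- frame_table(frames)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# fps=%d", attr(frames, "fps")), con)
  utils::write.csv(as.data.frame(frames), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write stimulus schedules
#'
#' Columns: \code{event_time_s, transition (on|off), trial_index}.
#'
#' @param path file path.
#' @export
read_stimulus_schedule <- function(path) {
  stimulus_schedule(read_csv_strict(path, c("event_time_s", "transition", "trial_index"),
                                    "stimulus schedule"))
}

#' @rdname read_stimulus_schedule
#' @param schedule a \code{\link{stimulus_schedule}}.
#' @export
write_stimulus_schedule <- function(schedule, path) {
  if (!inherits(schedule, "vmr_schedule")) schedule <- stimulus_schedule(schedule)
  write_csv_full(as.data.frame(schedule), path)
  invisible(path)
}

#' Read / write windowed activity sets (long form)
#'
#' Long-form CSV with one row per animal-by-event and relative second:
#' activity-table columns plus \code{stimulus, trial_index, event_time_s,
#' rel_second}.
#'
#' @param path file path.
#' @export
read_windowed_set <- function(path) {
  need <- c("animal_id", "stimulus", "trial_index", "event_time_s",
            "rel_second", "activity")
  df <- read_csv_strict(path, need, "windowed set")
  for (m in META_COLS) if (!m %in% names(df)) df[[m]] <- NA
  key <- paste(df$animal_id, df$event_time_s, sep = "\r")
  rel_seconds <- sort(unique(df$rel_second))
  ord <- order(key, df$rel_second)
  df <- df[ord, ]
  key <- key[ord]
  ukey <- unique(key)
  counts <- table(key)
  if (any(counts != length(rel_seconds))) {
    vmr_abort("windowed set file has incomplete windows", "vmr_schema_error")
  }
  values <- matrix(df$activity, nrow = length(ukey), ncol = length(rel_seconds),
                   byrow = TRUE, dimnames = list(NULL, as.character(rel_seconds)))
  first <- df[!duplicated(key), c("animal_id", "stimulus", "trial_index",
                                  "event_time_s", META_COLS)]
  rownames(first) <- NULL
  pre_len <- sum(rel_seconds <= 0)
  post_len <- sum(rel_seconds >= 1)
  structure(list(values = values, meta = first,
                 rel_seconds = as.integer(rel_seconds),
                 pre_len = pre_len, post_len = post_len, n_excluded = 0L),
            class = "vmr_windows")
}

#' @rdname read_windowed_set
#' @param windows a \code{vmr_windows} object.
#' @export
write_windowed_set <- function(windows, path) {
  n <- nrow(windows$values)
  k <- length(windows$rel_seconds)
  long <- cbind(
    windows$meta[rep(seq_len(n), each = k), , drop = FALSE],
    data.frame(rel_second = rep(windows$rel_seconds, n),
               activity = as.vector(t(windows$values))))
  rownames(long) <- NULL
  write_csv_full(long, path)
  invisible(path)
}
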