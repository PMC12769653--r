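# The pipeline state: a sample table plus role bindings and the ledger of
# steps applied so far. Every preprocessing verb takes a processor and
# returns a modified copy, reading the latest stage column and writing a
# new suffixed one, so all intermediate data survive.

#' Create a pupil processor
#'
#' Wraps a long-format sample table (one row per gaze sample) together with
#' the column bindings and sampling rate that every preprocessing step
#' needs. All statistics are computed independently within groups defined by
#' `trial_identifier`, so multiple participants can be processed in one
#' object as long as the identifier tuple is unique per trial.
#'
#' @param data a data.frame of samples, e.g. `read_asc(...)$samples`.
#' @param trial_identifier character vector of column(s) whose value tuple
#'   uniquely labels a trial (e.g. `c("block", "trial")`).
#' @param time_col,x_col,y_col,pupil_col column bindings; defaults match the
#'   reader's canonical schema.
#' @param sampling_rate sampling rate in Hz. If `NULL`, inferred as the
#'   reciprocal of the median inter-sample interval (time column assumed in
#'   milliseconds).
#' @return an object of class `pupil_processor`.
#' @export
pupil_processor <- function(data, trial_identifier,
                            time_col = "trialtime", x_col = "x",
                            y_col = "y", pupil_col = "pp",
                            sampling_rate = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(trial_identifier, time_col, x_col, y_col, pupil_col)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stopf("column(s) not in data: %s", paste(miss, collapse = ", "))
  if (is.null(sampling_rate)) {
    groups <- trial_row_groups(data, trial_identifier)
    dts <- unlist(lapply(groups, function(rows) diff(data[[time_col]][rows])),
                  use.names = FALSE)
    dts <- dts[is.finite(dts) & dts > 0]
    if (!length(dts)) stopf("cannot infer sampling rate; declare it explicitly")
    sampling_rate <- 1000 / stats::median(dts)
  }
  structure(list(data = data,
                 trial_identifier = trial_identifier,
                 time_col = time_col, x_col = x_col, y_col = y_col,
                 pupil_col = pupil_col,
                 sampling_rate = sampling_rate,
                 current = pupil_col,
                 steps = list()),
            class = "pupil_processor")
}

#' @export
print.pupil_processor <- function(x, ...) {
  ids <- trial_index(x$data, x$trial_identifier)
  cat(sprintf("<pupil_processor> %d samples, %d trial(s), %.6g Hz\n",
              nrow(x$data), nrow(ids), x$sampling_rate))
  cat(sprintf("  trial identifier: %s\n",
              paste(x$trial_identifier, collapse = ", ")))
  cat(sprintf("  current pupil column: %s\n", x$current))
  if (length(x$steps)) {
    cat("  steps:\n")
    for (s in x$steps)
      cat(sprintf("    %s -> %s (%s)\n", s$input, s$output, s$name))
  }
  invisible(x)
}

# The stage column every step reads from.
latest_column <- function(state) state$current

# Register a finished step: `stats` is a per-trial data.frame carrying the
# identifier columns plus n_missing_before / n_missing_after / succeeded and
# any step-specific fields (thresholds, baseline, interpolated ...).
add_step <- function(state, name, suffix, input, output, params, stats) {
  rec <- list(name = name, suffix = suffix, input = input, output = output,
              params = params, stats = stats)
  state$steps <- c(state$steps, list(rec))
  state$current <- output
  message(sprintf("[%s] created column '%s' from '%s' (%d/%d trial(s) ok)",
                  name, output, input, sum(stats$succeeded), nrow(stats)))
  state
}

# Output column name for a step; refuses to overwrite.
stage_output <- function(state, suffix) {
  out <- paste0(latest_column(state), "_", suffix)
  if (out %in% names(state$data))
    stopf("column '%s' already exists; steps never overwrite columns", out)
  out
}

# Skeleton per-trial stats frame (identifier columns only, trial order).
trial_stats_frame <- function(state) {
  trial_index(state$data, state$trial_identifier)
}

# Apply `fun(values, rows, key)` per trial to the latest stage column and
# collect a new column of the same length plus per-trial stat rows.
# fun must return list(values = ..., stats = named list).
map_trials <- function(state, fun, input = latest_column(state)) {
  groups <- trial_row_groups(state$data, state$trial_identifier)
  newcol <- rep(NA_real_, nrow(state$data))
  stat_rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    res <- fun(state$data[[input]][rows], rows, names(groups)[gi])
    newcol[rows] <- res$values
    stat_rows[[gi]] <- res$stats
  }
  ids <- trial_index(state$data, state$trial_identifier)
  stats <- cbind(ids, do.call(rbind, lapply(stat_rows, as.data.frame)))
  rownames(stats) <- NULL
  list(values = newcol, stats = stats)
}
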