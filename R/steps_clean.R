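# Cleaning steps: blink removal and resampling.

#' Detect blink intervals in a pupil trace
#'
#' Noise-based blink detection in the spirit of Hershman, Henik and Gera's
#' algorithm: recorders report a blink as a run of zero/missing pupil
#' samples, but the eyelid distorts the signal for some milliseconds on
#' either side (the closing and reopening ramps). Each zero/missing run is
#' therefore extended backward to the nearest preceding transition from
#' non-decreasing to decreasing signal, and forward to the first
#' non-increasing sample after recovery, on a lightly smoothed copy of the
#' trace. Runs closer than `merge_gap_ms` are merged first.
#'
#' @param trace numeric pupil series of one trial; zeros and `NA`s are both
#'   treated as signal loss.
#' @param times sample times in ms (same length).
#' @param sampling_rate Hz.
#' @param smooth_window_ms width of the moving average used to suppress
#'   sample noise before slope inspection (ms; 1 sample minimum).
#' @param merge_gap_ms runs of loss closer than this are one blink (ms).
#' @param onset_search_ms,offset_search_ms how far the ramps may extend
#'   beyond the zero/missing run (ms).
#' @return logical mask, `TRUE` for every sample inside a blink (runs plus
#'   ramps plus original `NA`/zero samples).
#' @export
detect_blinks <- function(trace, times, sampling_rate,
                          smooth_window_ms = 10, merge_gap_ms = 100,
                          onset_search_ms = 500, offset_search_ms = 500) {
  n <- length(trace)
  loss <- is.na(trace) | trace == 0
  mask <- loss
  if (!any(loss) || all(loss)) return(mask)
  runs <- true_runs(loss)
  # merge runs separated by less than the merge gap (in time)
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      gap <- times[runs$start[i]] - times[merged$end[nrow(merged)]]
      if (gap < merge_gap_ms) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  w <- max(1L, round(smooth_window_ms * sampling_rate / 1000))
  sm <- masked_moving_average(ifelse(loss, NA, trace), w)
  falling <- function(i)   # sample i sits on the closing ramp
    i >= 2L && !is.na(sm[i]) && !is.na(sm[i - 1L]) && sm[i] < sm[i - 1L]
  rising <- function(i)    # sample i sits on the reopening ramp
    i <= n - 1L && !is.na(sm[i]) && !is.na(sm[i + 1L]) && sm[i + 1L] > sm[i]
  for (ri in seq_len(nrow(runs))) {
    s <- runs$start[ri]; e <- runs$end[ri]
    # backward: include samples while the smoothed signal was still falling
    # into the blink; stop at the first non-decreasing (plateau) sample
    j <- s
    while (j > 1L && times[s] - times[j - 1L] <= onset_search_ms &&
           falling(j - 1L)) j <- j - 1L
    # forward: include samples while the smoothed signal is still rising out
    # of the blink; stop at the first non-increasing sample after recovery
    k <- e
    while (k < n && times[k + 1L] - times[e] <= offset_search_ms &&
           rising(k + 1L)) k <- k + 1L
    mask[j:k] <- TRUE
  }
  mask
}

# Centered NA-ignoring moving average (weights renormalised at edges/gaps).
masked_moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  off <- (0:(w - 1L)) - ((w - 1L) %/% 2L)
  num <- numeric(n); den <- numeric(n)
  ok <- !is.na(x)
  xv <- ifelse(ok, x, 0)
  for (o in off) {
    lo <- max(1L, 1L - o); hi <- min(n, n - o)
    if (lo > hi) next
    i <- lo:hi
    num[i] <- num[i] + xv[i + o] * ok[i + o]
    den[i] <- den[i] + ok[i + o]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!ok] <- NA_real_
  out
}

#' Remove blinks from the pupil signal
#'
#' Applies [detect_blinks()] per trial to the latest stage column and writes
#' a new column `<input>_db` in which every sample inside a detected blink
#' (the zero/missing run plus the eyelid closing and reopening ramps) is set
#' to `NA`. All other samples are copied unchanged. A trial whose trace is
#' entirely missing still gets the column (all `NA`) and is flagged as
#' failed in the step record.
#'
#' @param state a [pupil_processor()].
#' @param smooth_window_ms,merge_gap_ms,onset_search_ms,offset_search_ms
#'   passed to [detect_blinks()].
#' @return the updated processor.
#' @export
deblink <- function(state, smooth_window_ms = 10, merge_gap_ms = 100,
                    onset_search_ms = 500, offset_search_ms = 500) {
  stopifnot(inherits(state, "pupil_processor"))
  input <- latest_column(state)
  output <- stage_output(state, "db")
  tcol <- state$time_col
  res <- map_trials(state, function(x, rows, key) {
    tms <- state$data[[tcol]][rows]
    before <- sum(is.na(x))
    all_lost <- all(is.na(x) | x == 0)
    mask <- detect_blinks(x, tms, state$sampling_rate,
                          smooth_window_ms, merge_gap_ms,
                          onset_search_ms, offset_search_ms)
    v <- x
    v[mask] <- NA_real_
    list(values = v,
         stats = list(n_missing_before = before,
                      n_missing_after = sum(is.na(v)),
                      succeeded = !all_lost))
  }, input = input)
  state$data[[output]] <- res$values
  add_step(state, "deblink", "db", input, output,
           list(smooth_window_ms = smooth_window_ms,
                merge_gap_ms = merge_gap_ms,
                onset_search_ms = onset_search_ms,
                offset_search_ms = offset_search_ms),
           res$stats)
}

#' Downsample to a lower sampling rate
#'
#' Aggregates fixed non-overlapping windows of `sampling_rate / target_hz`
#' consecutive samples per trial. Numeric signal columns (x, y, pupil and
#' all stage columns) become the window mean ignoring missing values (a
#' fully missing window stays missing); times and non-numeric columns take
#' the window's first row. Intended for use after [deblink()], on signals
#' slow enough that no decimation filter is needed. A new stage column
#' `<input>_ds` carries the aggregated latest signal forward.
#'
#' @param state a [pupil_processor()].
#' @param target_hz target rate; must divide the current rate evenly.
#' @return the updated processor (fewer rows, updated `sampling_rate`).
#' @export
downsample <- function(state, target_hz) {
  stopifnot(inherits(state, "pupil_processor"))
  fs <- state$sampling_rate
  if (target_hz >= fs)
    stopf("target_hz (%g) must be below the current rate (%g)", target_hz, fs)
  factor <- fs / target_hz
  if (abs(factor - round(factor)) > 1e-6) {
    divs <- which(abs(fs / seq_len(floor(fs)) -
                        round(fs / seq_len(floor(fs)))) < 1e-6)
    near <- divs[which.min(abs(divs - target_hz))]
    stopf("target_hz %g does not divide %g Hz evenly; nearest divisor is %g Hz",
          target_hz, fs, near)
  }
  factor <- as.integer(round(factor))
  input <- latest_column(state)
  groups <- trial_row_groups(state$data, state$trial_identifier)
  num_cols <- names(state$data)[vapply(state$data, is.numeric, logical(1))]
  mean_cols <- setdiff(num_cols, c(state$time_col, "trackertime", "msgtime",
                                   state$trial_identifier))
  chunks <- vector("list", length(groups))
  stat_rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    g <- state$data[rows, , drop = FALSE]
    win <- (seq_len(nrow(g)) - 1L) %/% factor
    first <- !duplicated(win)
    out <- g[first, , drop = FALSE]
    for (cl in mean_cols) {
      m <- tapply(g[[cl]], win, function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
      out[[cl]] <- as.numeric(m)
    }
    chunks[[gi]] <- out
    stat_rows[[gi]] <- list(n_missing_before = sum(is.na(g[[input]])),
                            n_missing_after = sum(is.na(out[[input]])),
                            succeeded = TRUE)
  }
  newdata <- do.call(rbind, chunks)
  rownames(newdata) <- NULL
  output <- paste0(input, "_ds")
  newdata[[output]] <- newdata[[input]]
  state$data <- newdata
  state$sampling_rate <- target_hz
  ids <- trial_index(newdata, state$trial_identifier)
  stats <- cbind(ids, do.call(rbind, lapply(stat_rows, as.data.frame)))
  rownames(stats) <- NULL
  add_step(state, "downsample", "ds", input, output,
           list(target_hz = target_hz, factor = factor), stats)
}

#' Upsample to a higher sampling rate
#'
#' Lays a new regular time grid per trial at `target_hz` spanning the
#' trial's original time extent and linearly interpolates x, y, pupil and
#' stage columns between observed samples. Grid points that fall inside a
#' gap bounded by missing samples stay missing: interpolation only happens
#' within contiguous non-missing runs of the source signal, never across
#' them. Non-numeric columns carry the most recent original row's value
#' forward. A new stage column `<input>_us` carries the latest signal.
#'
#' @param state a [pupil_processor()].
#' @param target_hz target rate, above the current rate.
#' @return the updated processor.
#' @export
upsample <- function(state, target_hz) {
  stopifnot(inherits(state, "pupil_processor"))
  fs <- state$sampling_rate
  if (target_hz <= fs)
    stopf("target_hz (%g) must exceed the current rate (%g)", target_hz, fs)
  input <- latest_column(state)
  tcol <- state$time_col
  groups <- trial_row_groups(state$data, state$trial_identifier)
  num_cols <- names(state$data)[vapply(state$data, is.numeric, logical(1))]
  sig_cols <- setdiff(num_cols, c(tcol, "trackertime", "msgtime",
                                  state$trial_identifier))
  chunks <- vector("list", length(groups))
  stat_rows <- vector("list", length(groups))
  step_ms <- 1000 / target_hz
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    g <- state$data[rows, , drop = FALSE]
    if (nrow(g) < 2L)
      stopf("trial %s has fewer than 2 samples; cannot upsample",
            names(groups)[gi])
    t_old <- g[[tcol]]
    t_new <- seq(t_old[1L], t_old[length(t_old)], by = step_ms)
    carry <- findInterval(t_new, t_old)
    out <- g[pmax(carry, 1L), , drop = FALSE]
    out[[tcol]] <- t_new
    if ("trackertime" %in% names(out) && tcol != "trackertime")
      out$trackertime <- g$trackertime[1L] + (t_new - t_old[1L])
    for (cl in sig_cols)
      out[[cl]] <- interp_within_runs(t_old, g[[cl]], t_new)
    rownames(out) <- NULL
    chunks[[gi]] <- out
    stat_rows[[gi]] <- list(n_missing_before = sum(is.na(g[[input]])),
                            n_missing_after = sum(is.na(out[[input]])),
                            succeeded = TRUE)
  }
  newdata <- do.call(rbind, chunks)
  rownames(newdata) <- NULL
  output <- paste0(input, "_us")
  newdata[[output]] <- newdata[[input]]
  state$data <- newdata
  state$sampling_rate <- target_hz
  ids <- trial_index(newdata, state$trial_identifier)
  stats <- cbind(ids, do.call(rbind, lapply(stat_rows, as.data.frame)))
  rownames(stats) <- NULL
  add_step(state, "upsample", "us", input, output,
           list(target_hz = target_hz), stats)
}

# Linear interpolation restricted to contiguous non-missing runs of the
# source: a target time strictly between two source samples of which either
# is missing stays NA.
interp_within_runs <- function(t_old, v_old, t_new) {
  out <- rep(NA_real_, length(t_new))
  ok <- !is.na(v_old)
  if (!any(ok)) return(out)
  runs <- true_runs(ok)
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    sel <- t_new >= t_old[a] & t_new <= t_old[b]
    if (!any(sel)) next
    if (a == b) {
      out[sel] <- v_old[a]
    } else {
      out[sel] <- stats::approx(t_old[a:b], v_old[a:b], xout = t_new[sel],
                                method = "linear", ties = "ordered")$y
    }
  }
  out
}
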