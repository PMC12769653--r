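# Gap interpolation, baseline correction, and step chaining.

#' Interpolate missing samples
#'
#' Writes `<input>_ip`. Per trial: if the proportion of missing samples
#' exceeds `max_missing` (default 0.4, i.e. 40%), the column copies the
#' input unchanged and the trial is flagged as not interpolated — heavily
#' lossy trials produce untrustworthy interpolations. Otherwise interior
#' gaps are filled: linearly (chord between the gap's bounding samples) or
#' with a natural cubic spline fitted through all non-missing points of the
#' trial and evaluated inside the gaps. Leading and trailing missing runs
#' are never extrapolated; they stay missing.
#'
#' @param state a [pupil_processor()].
#' @param method `"linear"` (default) or `"cubic"`.
#' @param max_missing maximum tolerated missing proportion per trial.
#' @return the updated processor.
#' @export
interpolate_pupil <- function(state, method = c("linear", "cubic"),
                              max_missing = 0.4) {
  stopifnot(inherits(state, "pupil_processor"))
  method <- match.arg(method)
  input <- latest_column(state)
  output <- stage_output(state, "ip")
  tcol <- state$time_col
  res <- map_trials(state, function(x, rows, key) {
    tms <- state$data[[tcol]][rows]
    miss <- is.na(x)
    prop <- mean(miss)
    ok <- which(!miss)
    if (prop > max_missing || length(ok) < 2L) {
      return(list(values = x,
                  stats = list(n_missing_before = sum(miss),
                               n_missing_after = sum(miss),
                               succeeded = length(ok) >= 2L,
                               interpolated = FALSE,
                               prop_missing = prop)))
    }
    v <- x
    interior <- which(miss)
    interior <- interior[interior > ok[1L] & interior < ok[length(ok)]]
    if (length(interior)) {
      v[interior] <- if (method == "linear") {
        stats::approx(tms[ok], x[ok], xout = tms[interior],
                      method = "linear", ties = "ordered")$y
      } else {
        f <- stats::splinefun(tms[ok], x[ok], method = "natural")
        f(tms[interior])
      }
    }
    list(values = v,
         stats = list(n_missing_before = sum(miss),
                      n_missing_after = sum(is.na(v)),
                      succeeded = TRUE,
                      interpolated = TRUE,
                      prop_missing = prop))
  }, input = input)
  state$data[[output]] <- res$values
  add_step(state, "interpolate", "ip", input, output,
           list(method = method, max_missing = max_missing),
           res$stats)
}

#' Baseline-correct the pupil signal
#'
#' Expresses pupil size relative to a pre-stimulus baseline, writing
#' `<input>_bc`. The baseline window can be given as an event label (the
#' samples whose `event_col` value equals `event`; typically the fixation
#' period preceding the stimulus), as a numeric `c(t0, t1)` range on the
#' trial clock applied to every trial, or as a per-trial data.frame with
#' the identifier columns plus `t0`, `t1`. Within the window, the baseline
#' `b` is the mean of the last `last_k` samples (by position), ignoring
#' missing values; if fewer than 10% of those samples are non-missing the
#' trial is flagged rather than silently averaged. The corrected signal is
#' `p - b` (subtractive, the default — divisive correction is prone to
#' producing outlier traces) or `p / b`; a divisive baseline of 0 flags the
#' trial. Flagged trials get an all-missing column.
#'
#' @param state a [pupil_processor()].
#' @param event event label selecting the window rows.
#' @param event_col column holding the event label (default `"event"`).
#' @param window alternative to `event`: numeric `c(t0, t1)` or a
#'   per-trial data.frame of ranges.
#' @param last_k number of trailing window samples averaged (default 100).
#' @param method `"subtractive"` or `"divisive"`.
#' @return the updated processor; per-trial baselines are stored in the
#'   step record.
#' @export
baseline_correct <- function(state, event = NULL, event_col = "event",
                             window = NULL, last_k = 100,
                             method = c("subtractive", "divisive")) {
  stopifnot(inherits(state, "pupil_processor"))
  method <- match.arg(method)
  if (is.null(event) && is.null(window))
    stopf("provide either 'event' or 'window'")
  input <- latest_column(state)
  output <- stage_output(state, "bc")
  tcol <- state$time_col
  win_df <- if (is.data.frame(window)) window else NULL
  res <- map_trials(state, function(x, rows, key) {
    in_win <- if (!is.null(event)) {
      evs <- state$data[[event_col]][rows]
      if (!event %in% evs)
        stopf("baseline window unresolvable: no samples with %s == %s in trial %s",
              event_col, dQuote(event), key)
      evs == event
    } else {
      tms <- state$data[[tcol]][rows]
      rng <- if (!is.null(win_df)) {
        wkeys <- trial_key(win_df, state$trial_identifier)
        hit <- match(key, wkeys)
        if (is.na(hit))
          stopf("baseline window unresolvable: trial %s missing from 'window'", key)
        c(win_df$t0[hit], win_df$t1[hit])
      } else window
      if (rng[1] > max(tms) || rng[2] < min(tms))
        stopf("baseline window [%g, %g] lies outside trial %s", rng[1], rng[2], key)
      tms >= rng[1] & tms <= rng[2]
    }
    wvals <- x[in_win]
    wvals <- wvals[max(1L, length(wvals) - last_k + 1L):length(wvals)]
    n_ok <- sum(!is.na(wvals))
    b <- if (n_ok > 0) mean(wvals, na.rm = TRUE) else NA_real_
    flagged <- n_ok < max(1, 0.1 * last_k) ||
      (method == "divisive" && !is.na(b) && b == 0)
    if (flagged || is.na(b)) {
      return(list(values = rep(NA_real_, length(x)),
                  stats = list(n_missing_before = sum(is.na(x)),
                               n_missing_after = length(x),
                               succeeded = FALSE, baseline = b)))
    }
    v <- if (method == "subtractive") x - b else x / b
    list(values = v,
         stats = list(n_missing_before = sum(is.na(x)),
                      n_missing_after = sum(is.na(v)),
                      succeeded = TRUE, baseline = b))
  }, input = input)
  state$data[[output]] <- res$values
  add_step(state, "baseline_correct", "bc", input, output,
           list(event = event, window = if (is.numeric(window)) window else NULL,
                last_k = last_k, method = method),
           res$stats)
}

# Registry mapping config/CLI step names onto the pipeline verbs.
step_registry <- function() {
  list(deblink = deblink,
       downsample = downsample,
       upsample = upsample,
       artifact_rejection = artifact_rejection,
       filter_position = filter_position,
       smooth = smooth_pupil,
       interpolate = interpolate_pupil,
       baseline_correct = baseline_correct)
}

#' Chain preprocessing steps
#'
#' Applies an ordered list of steps, each a `list(op = <name>, ...params)`
#' (or a bare step name for defaults), producing exactly the same result as
#' calling the verbs in sequence; stage suffixes accumulate
#' (`pp -> pp_db -> pp_db_ar -> ...`). The first failing step aborts with a
#' classed error (`pupilpipe_chain_error`) naming the step; the partial
#' state up to that point is attached to the condition as `$state`.
#'
#' @param state a [pupil_processor()].
#' @param steps list of step descriptions; an empty list returns the state
#'   unchanged.
#' @return the updated processor.
#' @export
chain_steps <- function(state, steps) {
  stopifnot(inherits(state, "pupil_processor"))
  reg <- step_registry()
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.character(s)) s <- list(op = s)
    op <- s$op
    if (is.null(op) || !op %in% names(reg))
      stopf("unknown step name: %s", op %||% "<missing>")
    params <- s[setdiff(names(s), "op")]
    state <- tryCatch(
      do.call(reg[[op]], c(list(state), params)),
      error = function(e) {
        cond <- structure(
          class = c("pupilpipe_chain_error", "error", "condition"),
          list(message = sprintf("step %d ('%s') failed: %s",
                                 i, op, conditionMessage(e)),
               call = NULL, state = state, step = op))
        stop(cond)
      })
  }
  state
}
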