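# Smoothing: Hann-window convolution (default), rolling mean, or a
# zero-phase Butterworth low-pass. All three operate strictly within
# contiguous non-missing runs so that missing samples stay missing and
# never bleed into their neighbours.

# Hann window of length w, normalised to unit sum.
hann_window <- function(w) {
  stopifnot(w >= 3)
  k <- 0:(w - 1)
  h <- 0.5 * (1 - cos(2 * pi * k / (w - 1)))
  h / sum(h)
}

# Masked centred convolution over one contiguous run: weights falling
# outside the run are dropped and the remainder renormalised, which keeps
# unit DC gain at run edges.
convolve_run <- function(x, weights) {
  n <- length(x)
  w <- length(weights)
  off <- (0:(w - 1)) - ((w - 1) %/% 2)
  num <- numeric(n); den <- numeric(n)
  for (j in seq_len(w)) {
    o <- off[j]
    lo <- max(1L, 1L - o); hi <- min(n, n - o)
    if (lo > hi) next
    i <- lo:hi
    num[i] <- num[i] + weights[j] * x[i + o]
    den[i] <- den[i] + weights[j]
  }
  num / den
}

# Smooth one trial trace: apply `runfun` to every contiguous non-missing
# run, leave NAs in place.
smooth_by_runs <- function(x, runfun) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  runs <- true_runs(ok)
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    out[idx] <- runfun(x[idx])
  }
  out
}

#' Smooth the pupil signal
#'
#' Writes `<input>_sm`. The default is a Hann (raised-cosine) window of
#' 100 samples, convolved centred with weights normalised to unit sum, so
#' a constant trace maps to itself. `"rolling_mean"` uses flat weights of
#' the same length. `"butterworth"` applies a zero-phase (forward-backward)
#' low-pass filter, default order 3 with a 4 Hz cutoff. Every method is
#' computed independently on each contiguous non-missing run of each trial:
#' missing samples stay missing, window weights that would reach across a
#' gap or run edge are dropped and the rest renormalised.
#'
#' If no non-missing run of a trial is at least `window` samples long
#' (window methods), the trial's output is entirely missing and the trial
#' is flagged as failed.
#'
#' @param state a [pupil_processor()].
#' @param method `"hann"`, `"rolling_mean"` or `"butterworth"`.
#' @param window window length in samples for the window methods
#'   (default 100; minimum 3).
#' @param butter_order,butter_cutoff_hz Butterworth order and cutoff; the
#'   cutoff must be below the Nyquist frequency.
#' @return the updated processor.
#' @export
smooth_pupil <- function(state, method = c("hann", "rolling_mean",
                                           "butterworth"),
                         window = 100, butter_order = 3,
                         butter_cutoff_hz = 4) {
  stopifnot(inherits(state, "pupil_processor"))
  method <- match.arg(method)
  input <- latest_column(state)
  output <- stage_output(state, "sm")
  if (method %in% c("hann", "rolling_mean") && window < 3)
    stopf("'window' must be at least 3 samples")
  runfun <- switch(method,
    hann = {
      wts <- hann_window(window)
      function(x) convolve_run(x, wts)
    },
    rolling_mean = {
      wts <- rep(1 / window, window)
      function(x) convolve_run(x, wts)
    },
    butterworth = {
      co <- butter_lowpass(butter_order, butter_cutoff_hz,
                           state$sampling_rate)
      function(x) if (length(x) >= 2) filtfilt_zero_phase(co$b, co$a, x)
                  else x
    })
  res <- map_trials(state, function(x, rows, key) {
    ok <- !is.na(x)
    longest <- if (any(ok)) max(rle(ok)$lengths[rle(ok)$values]) else 0L
    if (method %in% c("hann", "rolling_mean") && longest < window) {
      return(list(values = rep(NA_real_, length(x)),
                  stats = list(n_missing_before = sum(!ok),
                               n_missing_after = length(x),
                               succeeded = FALSE)))
    }
    v <- smooth_by_runs(x, runfun)
    list(values = v,
         stats = list(n_missing_before = sum(!ok),
                      n_missing_after = sum(is.na(v)),
                      succeeded = TRUE))
  }, input = input)
  state$data[[output]] <- res$values
  add_step(state, "smooth", "sm", input, output,
           list(method = method, window = window,
                butter_order = butter_order,
                butter_cutoff_hz = butter_cutoff_hz),
           res$stats)
}
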