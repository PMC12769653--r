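# Synthetic recordings with injected ground truth. The trace model —
# a flat baseline plus a gamma-shaped event-locked dilation and Gaussian
# sample noise, with blinks overwriting the signal as a linear closing
# ramp, a zero plateau and a linear reopening ramp — is test scaffolding:
# it makes every downstream operation checkable against known truth, and
# makes no claim of physiological validity.

#' Specify a synthetic pupil trace
#'
#' @param duration_ms trial length (default 3000 ms).
#' @param sampling_rate Hz; the ASC emitter needs 1000/sampling_rate to be
#'   a whole number of ms (e.g. 1000, 500, 250).
#' @param baseline baseline pupil level in recorder units (default 1000,
#'   a typical EyeLink area value).
#' @param bump event-locked dilation: list with `onset_ms`, `amplitude`,
#'   and the gamma shape parameters `shape` and `tmax_ms` (peak latency).
#'   Defaults follow the common pupil-response parametrisation
#'   (shape 10.1, peak 930 ms).
#' @param noise_sd Gaussian sample noise sd (default 5 units).
#' @param blinks list of blinks, each
#'   `list(onset_ms, close_ramp_ms, closed_ms, reopen_ramp_ms)`.
#' @param spikes list of impulse artifacts, each `list(time_ms, magnitude)`.
#' @param seed mandatory integer seed; same spec + seed is bit-identical.
#' @return an object of class `trace_spec`.
#' @export
trace_spec <- function(duration_ms = 3000, sampling_rate = 1000,
                       baseline = 1000,
                       bump = list(onset_ms = 1000, amplitude = 100,
                                   shape = 10.1, tmax_ms = 930),
                       noise_sd = 5, blinks = list(), spikes = list(),
                       seed) {
  if (missing(seed)) stopf("'seed' is mandatory for reproducibility")
  for (b in blinks) {
    len <- b$close_ramp_ms + b$closed_ms + b$reopen_ramp_ms
    if (b$onset_ms < 0 || b$onset_ms >= duration_ms)
      stopf("blink onset %g ms outside the trial", b$onset_ms)
    if (len <= 0) stopf("blink has non-positive length")
  }
  if (length(blinks) > 1L) {
    on <- vapply(blinks, `[[`, numeric(1), "onset_ms")
    en <- on + vapply(blinks, function(b)
      b$close_ramp_ms + b$closed_ms + b$reopen_ramp_ms, numeric(1))
    o <- order(on)
    if (any(on[o][-1] < en[o][-length(en)]))
      stopf("blinks overlap")
  }
  structure(list(duration_ms = duration_ms, sampling_rate = sampling_rate,
                 baseline = baseline, bump = bump, noise_sd = noise_sd,
                 blinks = blinks, spikes = spikes, seed = seed),
            class = "trace_spec")
}

# Gamma-shaped dilation, peak value 1 at t = tmax.
pupil_bump <- function(t_ms, onset_ms, shape, tmax_ms) {
  x <- (t_ms - onset_ms) / tmax_ms
  out <- numeric(length(t_ms))
  pos <- x > 0
  out[pos] <- x[pos]^shape * exp(shape * (1 - x[pos]))
  out
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic pupil trace with ground truth
#'
#' Builds `baseline + bump + noise`, then overwrites each declared blink
#' with a strictly decreasing closing ramp, a zero plateau, and a strictly
#' increasing reopening ramp (ramp samples lie strictly between 0 and the
#' surrounding signal), and finally adds spike impulses. The ground truth
#' records the clean (pre-blink, pre-spike) trace, every blink interval
#' including its ramps, and the spike sample indices.
#'
#' @param spec a [trace_spec()].
#' @return list with `times` (ms), `trace`, and `truth` (list: `clean`,
#'   `blink_mask`, `blink_intervals` data.frame, `spike_idx`, `baseline`,
#'   `noise_sd`).
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  dt <- 1000 / spec$sampling_rate
  times <- seq(0, spec$duration_ms - dt, by = dt)
  n <- length(times)
  clean <- spec$baseline +
    spec$bump$amplitude * pupil_bump(times, spec$bump$onset_ms,
                                     spec$bump$shape, spec$bump$tmax_ms)
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd)) else numeric(n)
  trace <- clean + noise
  blink_mask <- rep(FALSE, n)
  intervals <- data.frame(start = integer(0), end = integer(0))
  for (b in spec$blinks) {
    i0 <- which(times >= b$onset_ms)[1]
    r1 <- round(b$close_ramp_ms / dt)
    pl <- round(b$closed_ms / dt)
    r2 <- round(b$reopen_ramp_ms / dt)
    idx_end <- min(n, i0 + as.integer(r1 + pl + r2) - 1L)
    v_pre <- if (i0 > 1L) trace[i0 - 1L] else spec$baseline
    v_post <- if (idx_end < n) trace[idx_end + 1L] else spec$baseline
    seg <- c(if (r1 > 0) v_pre * (r1:1) / (r1 + 1),
             rep(0, pl),
             if (r2 > 0) v_post * (1:r2) / (r2 + 1))
    seg <- seg[seq_len(idx_end - i0 + 1L)]
    trace[i0:idx_end] <- seg
    blink_mask[i0:idx_end] <- TRUE
    intervals <- rbind(intervals, data.frame(start = as.integer(i0),
                                             end = as.integer(idx_end)))
  }
  spike_idx <- integer(0)
  for (s in spec$spikes) {
    i <- which.min(abs(times - s$time_ms))
    if (!blink_mask[i]) {
      trace[i] <- trace[i] + s$magnitude
      spike_idx <- c(spike_idx, i)
    }
  }
  list(times = times, trace = trace,
       truth = list(clean = clean, blink_mask = blink_mask,
                    blink_intervals = intervals, spike_idx = spike_idx,
                    baseline = spec$baseline, noise_sd = spec$noise_sd))
}

#' Emit a synthetic EyeLink ASC recording
#'
#' Writes an ASC text file — header chatter, MSG rows, tab-separated
#' integer-timestamp sample rows, EFIX/EBLINK event rows, and discardable
#' inter-trial samples — that [read_asc()] must parse back exactly. Each
#' trial gets a start boundary message at its first sample, a mid-trial
#' phase message at the bump onset (so an `event` column distinguishes the
#' fixation from the stimulus period), and a stop boundary message at its
#' last sample. During blink plateaus x/y are written as `"."` (track
#' loss) while pp is written as 0, matching recorder behaviour.
#'
#' @param trials list of per-trial descriptions:
#'   `list(trace = trace_spec(...), fields = list(block = "A", trial = 1))`.
#'   `fields` must cover every marker field except the first two (marker +
#'   event), which the schedule fills in.
#' @param spec a [marker_spec()] whose first two fields are the marker verb
#'   and the event phase (as in `"start fixation A 4"`).
#' @param path output file.
#' @param start_event,stimulus_event,stop_event event-phase words used in
#'   the schedule; the start/stop boundary prefixes of `spec` must equal
#'   `paste(verb, event)` for the respective rows.
#' @param tracker_origin recorder clock of the first sample (ms).
#' @param gap_ms inter-trial gap filled with junk samples that the reader
#'   must discard.
#' @param screen `c(width, height)` used for gaze jitter around centre.
#' @return list with `path` and `truth`: per trial key, the sample count,
#'   emitted times/x/y/pp (as re-parsed numbers, so comparisons are exact),
#'   the message schedule, blink/spike truth, and event intervals.
#' @export
generate_recording_asc <- function(trials, spec, path,
                                   stimulus_event = "letters",
                                   tracker_origin = 1000000,
                                   gap_ms = 100,
                                   screen = c(1920, 1080)) {
  stopifnot(inherits(spec, "marker_spec"), is.list(trials))
  lines <- c("** CONVERTED FROM synthetic recording",
             "** DATE: synthetic",
             "START\t0 \tLEFT\tSAMPLES\tEVENTS")
  truth <- list()
  clock <- tracker_origin
  fmt1 <- function(v) formatC(v, format = "f", digits = 1)
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    g <- generate_trace(tr$trace)
    dt <- 1000 / tr$trace$sampling_rate
    stopifnot(abs(dt - round(dt)) < 1e-9)
    dt <- as.integer(round(dt))
    n <- length(g$trace)
    tt <- clock + as.integer(round(g$times))
    xy <- with_seed(tr$trace$seed + 1L,
                    list(x = screen[1] / 2 + stats::rnorm(n, 0, 30),
                         y = screen[2] / 2 + stats::rnorm(n, 0, 30)))
    pp_chr <- fmt1(g$trace)
    zero_plateau <- g$trace == 0
    x_chr <- ifelse(zero_plateau, ".", fmt1(xy$x))
    y_chr <- ifelse(zero_plateau, ".", fmt1(xy$y))
    pp_chr[zero_plateau] <- "0.0"

    verb_event <- function(boundary) strsplit(boundary, spec$delimiter,
                                              fixed = TRUE)[[1]]
    mk_msg <- function(time, verb, event) {
      vals <- c(list(verb, event), unname(tr$fields))
      names(vals) <- spec$field_names
      list(time = time, text = format_marker(vals, spec))
    }
    sv <- verb_event(spec$start_message)
    ev <- verb_event(spec$stop_message)
    sched <- list(
      mk_msg(tt[1], sv[1], sv[2]),
      mk_msg(clock + as.integer(round(tr$trace$bump$onset_ms)),
             sv[1], stimulus_event),
      mk_msg(tt[n], ev[1], ev[2]))
    msg_lines <- vapply(sched, function(m)
      sprintf("MSG\t%d %s", m$time, m$text), character(1))
    sample_lines <- sprintf("%d\t%s\t%s\t%s\t...", tt, x_chr, y_chr, pp_chr)

    # recorder events: one fixation spanning the pre-stimulus period,
    # one EBLINK per injected blink plateau; S* lines must be ignored
    fix_end <- clock + as.integer(round(tr$trace$bump$onset_ms)) - dt
    ev_lines <- c(sprintf("SFIX L   %d", tt[1]),
                  sprintf("EFIX L   %d\t%d\t%d\t  %s\t  %s\t  %d",
                          tt[1], fix_end, fix_end - tt[1],
                          fmt1(screen[1] / 2), fmt1(screen[2] / 2),
                          as.integer(round(tr$trace$baseline))))
    ev_truth <- data.frame(kind = "fixation", start_time = tt[1],
                           end_time = fix_end)
    bl <- g$truth$blink_intervals
    for (bi in seq_len(nrow(bl))) {
      zs <- which(zero_plateau & seq_len(n) >= bl$start[bi] &
                    seq_len(n) <= bl$end[bi])
      if (!length(zs)) next
      ev_lines <- c(ev_lines,
                    sprintf("SBLINK L %d", tt[zs[1]]),
                    sprintf("EBLINK L %d\t%d\t%d", tt[zs[1]],
                            tt[zs[length(zs)]], tt[zs[length(zs)]] - tt[zs[1]]))
      ev_truth <- rbind(ev_truth,
                        data.frame(kind = "blink", start_time = tt[zs[1]],
                                   end_time = tt[zs[length(zs)]]))
    }
    # interleave in time order: messages before samples at equal times
    block <- c(msg_lines[1],
               sample_lines[tt < sched[[2]]$time],
               msg_lines[2],
               sample_lines[tt >= sched[[2]]$time & tt < tt[n]],
               ev_lines,
               sample_lines[n],
               msg_lines[3])
    lines <- c(lines, block)
    key <- paste(unlist(tr$fields), collapse = "|")
    truth[[key]] <- list(
      n_samples = n,
      trackertime = tt,
      x = ifelse(zero_plateau, NA_real_, as.numeric(fmt1(xy$x))),
      y = ifelse(zero_plateau, NA_real_, as.numeric(fmt1(xy$y))),
      pp = as.numeric(pp_chr),
      messages = data.frame(
        time = vapply(sched, `[[`, numeric(1), "time"),
        text = vapply(sched, `[[`, character(1), "text")),
      events = ev_truth,
      trace_truth = g$truth,
      times_ms = g$times)
    clock <- tt[n] + dt
    # inter-trial junk the reader must drop
    junk_t <- seq(clock + 1, clock + gap_ms, by = max(1, dt))
    lines <- c(lines, sprintf("%d\t%s\t%s\t%s\t...", as.integer(junk_t),
                              fmt1(screen[1] / 2), fmt1(screen[2] / 2),
                              fmt1(900)))
    clock <- as.integer(junk_t[length(junk_t)]) + dt
  }
  lines <- c(lines, "END\t0 \tSAMPLES\tEVENTS")
  writeLines(lines, path)
  list(path = path, truth = truth)
}

#' Generate fixations with known AOI membership
#'
#' Samples `per_aoi_counts[[name]]` fixations uniformly inside each named
#' AOI (rejection sampling from the polygon's bounding box, excluding any
#' AOI earlier in declaration order so that first-wins assignment recovers
#' the labels exactly) plus `outside_count` fixations inside the canvas but
#' outside every AOI. Durations are drawn uniformly from `duration_range`.
#'
#' @param aois a flat [aoi_set()].
#' @param per_aoi_counts named list/vector of counts per AOI name.
#' @param outside_count fixations outside all AOIs.
#' @param duration_range `c(min, max)` ms.
#' @param canvas `c(width, height)` pixels.
#' @param seed integer seed.
#' @param trial_id value for the `trial_id` column.
#' @return data.frame `x`, `y`, `duration`, `trial_id`, `truth_aoi`.
#' @export
generate_fixations <- function(aois, per_aoi_counts, outside_count = 0,
                               duration_range = c(100, 500),
                               canvas = c(1920, 1080), seed, trial_id = 1) {
  stopifnot(inherits(aois, "aoi_set"), !isTRUE(attr(aois, "nested")))
  if (missing(seed)) stopf("'seed' is mandatory")
  nms <- names(per_aoi_counts)
  stopifnot(all(nms %in% names(aois)))
  with_seed(seed, {
    rows <- list()
    sample_in <- function(test, label, count) {
      got <- 0L
      tries <- 0L
      while (got < count) {
        tries <- tries + 1L
        if (tries > 20000L * max(1L, count))
          stopf("rejection sampling failed for '%s' (near-zero area?)", label)
        p <- c(stats::runif(1, 0, canvas[1]), stats::runif(1, 0, canvas[2]))
        if (test(p)) {
          got <- got + 1L
          rows[[length(rows) + 1L]] <<- data.frame(
            x = p[1], y = p[2],
            duration = stats::runif(1, duration_range[1], duration_range[2]),
            trial_id = trial_id, truth_aoi = label)
        }
      }
    }
    for (ni in seq_along(nms)) {
      nm <- nms[ni]
      prior <- names(aois)[seq_len(match(nm, names(aois)) - 1L)]
      sample_in(function(p)
        point_in_polygon(p, aois[[nm]]) &&
          !any(vapply(prior, function(q)
            point_in_polygon(p, aois[[q]]), logical(1))),
        nm, per_aoi_counts[[nm]])
    }
    if (outside_count > 0)
      sample_in(function(p)
        !any(vapply(names(aois), function(q)
          point_in_polygon(p, aois[[q]]), logical(1))),
        "outside", outside_count)
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(x = numeric(0), y = numeric(0),
                           duration = numeric(0), trial_id = trial_id[0],
                           truth_aoi = character(0))
    rownames(out) <- NULL
    out
  })
}
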