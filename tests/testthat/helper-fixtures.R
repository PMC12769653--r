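# Shared fixture builders.

default_marker_spec <- function() {
  marker_spec(
    fields = c(marker = "text", event = "text", block = "text",
               trial = "integer"),
    start_message = "start fixation",
    stop_message = "end feedback")
}

# Processor around bare traces (1 ms steps by default), one trial each.
make_state <- function(traces, dt = 1, event = NULL) {
  chunks <- lapply(seq_along(traces), function(i) {
    n <- length(traces[[i]])
    df <- data.frame(trial = i, trialtime = (seq_len(n) - 1) * dt,
                     x = 960, y = 540, pp = traces[[i]])
    if (!is.null(event)) df$event <- event[[i]]
    df
  })
  pupil_processor(do.call(rbind, chunks), trial_identifier = "trial",
                  sampling_rate = 1000 / dt)
}

# A small two-trial synthetic recording on disk plus its truth.
make_recording <- function(n_trials = 2, duration_ms = 2000,
                           sampling_rate = 1000, noise_sd = 3,
                           blinks_for = integer(0), seed = 42,
                           path = tempfile(fileext = ".asc")) {
  spec <- default_marker_spec()
  trials <- lapply(seq_len(n_trials), function(i) {
    bl <- if (i %in% blinks_for)
      list(list(onset_ms = duration_ms * 0.6, close_ramp_ms = 20,
                closed_ms = 60, reopen_ramp_ms = 20)) else list()
    list(trace = trace_spec(duration_ms = duration_ms,
                            sampling_rate = sampling_rate,
                            noise_sd = noise_sd, blinks = bl,
                            seed = seed + i),
         fields = list(block = "A", trial = i))
  })
  rec <- generate_recording_asc(trials, spec, path)
  rec$spec <- spec
  rec
}

square_aois <- function() {
  aoi_set(list(
    left = rbind(c(100, 100), c(700, 100), c(700, 700), c(100, 700),
                 c(100, 100)),
    right = rbind(c(1000, 100), c(1600, 100), c(1600, 700), c(1000, 700),
                  c(1000, 100))))
}
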