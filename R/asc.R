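# EyeLink ASC reader. Dialect: a line whose first token parses as an integer
# is a gaze sample; lines starting with MSG / EFIX / ESACC / EBLINK are
# events; everything else (headers, SFIX/SSACC/SBLINK, calibration chatter)
# is ignored. Only samples between a start-boundary message and the next
# stop-boundary message are kept.

#' Read an EyeLink ASC recording
#'
#' Parses the text export of an EyeLink recording into a tidy per-sample
#' table plus a table of recorder-detected fixation/saccade/blink events,
#' segmented into trials by the boundary messages of a [marker_spec()].
#'
#' Each retained sample is paired with the most recent marker message at or
#' before its timestamp; that message is parsed under the grammar into one
#' column per declared field, so dynamic fields (event phase, block, trial
#' number) travel with every sample. Messages that do not conform to the
#' grammar (calibration chatter etc.) are ignored for pairing. `trialtime`
#' is re-zeroed at the first sample of each trial. Track-loss samples
#' (`.` in the x/y fields) keep their row with `x`/`y`/`pp` set to `NA`.
#' Raw pupil zeros are preserved; they are only neutralised by [deblink()].
#'
#' Binocular recordings are reduced to a single eye (`eye`, default left).
#' A start message with no matching stop before end of file, or a second
#' start before a stop, drops the open trial with a warning.
#'
#' @param path path to the ASC file.
#' @param spec a [marker_spec()] declaring the message grammar and trial
#'   boundaries.
#' @param eye `"left"` or `"right"`; used only when sample rows carry both
#'   eyes.
#' @return a list with components `samples` (data.frame: `trialtime`,
#'   `trackertime`, `x`, `y`, `pp`, `msg`, `msgtime`, one column per marker
#'   field, constant columns), `events` (data.frame: `kind`, `start_time`,
#'   `end_time`, `duration`, geometry columns, trial identifier fields) and
#'   `n_skipped` (malformed sample rows dropped).
#' @export
read_asc <- function(path, spec, eye = c("left", "right")) {
  stopifnot(inherits(spec, "marker_spec"))
  eye <- match.arg(eye)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first_tok <- sub("^\\s*(\\S+).*$", "\\1", lines)

  is_sample <- grepl("^[0-9]+$", first_tok)
  is_msg <- first_tok == "MSG"
  is_evt <- first_tok %in% c("EFIX", "ESACC", "EBLINK")

  msgs <- parse_msg_lines(lines[is_msg])
  smp <- parse_sample_lines(lines[is_sample], eye)
  events_raw <- parse_event_lines(lines[is_evt])

  # only marker messages conforming to the grammar take part in pairing
  conform <- vapply(msgs$text, function(m)
    tryCatch({parse_marker(m, spec); TRUE}, error = function(e) FALSE),
    logical(1), USE.NAMES = FALSE)
  mk <- msgs[conform, , drop = FALSE]

  trials <- segment_trials(mk, spec)
  if (nrow(trials) == 0L) {
    warnf("no start/stop boundary pair found in %s; returning empty tables", path)
    return(list(samples = empty_samples(spec), events = empty_events(spec),
                n_skipped = smp$n_skipped))
  }

  sample_chunks <- vector("list", nrow(trials))
  event_chunks <- vector("list", nrow(trials))
  for (ti in seq_len(nrow(trials))) {
    t0 <- trials$start_time[ti]; t1 <- trials$stop_time[ti]
    keep <- smp$data$trackertime >= t0 & smp$data$trackertime <= t1
    s <- smp$data[keep, , drop = FALSE]
    if (nrow(s) == 0L) next
    # most recent conforming message at or before each sample
    in_tr <- mk$time >= t0 & mk$time <= t1
    mtr <- mk[in_tr, , drop = FALSE]
    idx <- findInterval(s$trackertime, mtr$time)
    s$msg <- mtr$text[idx]
    s$msgtime <- mtr$time[idx]
    fields <- parsed_fields_for(mtr$text, spec)
    for (fn in spec$field_names) s[[fn]] <- fields[[fn]][idx]
    s$trialtime <- s$trackertime - s$trackertime[1L]
    sample_chunks[[ti]] <- s[c("trialtime", "trackertime", "x", "y", "pp",
                               "msg", "msgtime", spec$field_names)]
    if (nrow(events_raw)) {
      ein <- events_raw$start_time >= t0 & events_raw$end_time <= t1
      ev <- events_raw[ein, , drop = FALSE]
      if (nrow(ev)) {
        start_fields <- parse_marker(trials$start_msg[ti], spec)
        for (fn in spec$field_names) ev[[fn]] <- start_fields[[fn]]
        event_chunks[[ti]] <- ev
      }
    }
  }
  samples <- do.call(rbind, sample_chunks)
  events <- do.call(rbind, event_chunks)
  if (is.null(samples)) samples <- empty_samples(spec)
  if (is.null(events)) events <- empty_events(spec)
  rownames(samples) <- NULL; rownames(events) <- NULL
  for (nm in names(spec$constant_columns %||% list())) {
    samples[[nm]] <- spec$constant_columns[[nm]]
    if (nrow(events)) events[[nm]] <- spec$constant_columns[[nm]]
  }
  if (smp$n_skipped > 0L)
    warnf("%d malformed sample row(s) skipped in %s", smp$n_skipped, path)
  list(samples = samples, events = events, n_skipped = smp$n_skipped)
}

parse_msg_lines <- function(lines) {
  if (!length(lines))
    return(data.frame(time = numeric(0), text = character(0)))
  body <- sub("^\\s*MSG\\s+", "", lines)
  time <- as.numeric(sub("^(\\S+).*$", "\\1", body))
  text <- sub("^\\S+\\s+", "", body)
  ok <- !is.na(time) & text != body
  out <- data.frame(time = time[ok], text = trimws(text[ok]),
                    stringsAsFactors = FALSE)
  out[order(out$time), , drop = FALSE]
}

# Sample rows: <time> then a leading run of data tokens, each numeric or "."
# (track loss). 3 data tokens = monocular x/y/pp; >= 6 = binocular
# (left triplet then right). Trailing flag tokens such as "..." are ignored.
parse_sample_lines <- function(lines, eye) {
  empty <- data.frame(trackertime = numeric(0), x = numeric(0),
                      y = numeric(0), pp = numeric(0))
  if (!length(lines)) return(list(data = empty, n_skipped = 0L))
  toks <- strsplit(trimws(lines), "\\s+")
  parse_one <- function(tk) {
    dat <- tk[-1L]
    is_data <- dat == "." | grepl("^-?[0-9]*\\.?[0-9]+$", dat)
    n <- match(FALSE, is_data, nomatch = length(dat) + 1L) - 1L
    if (n < 3L) return(rep(NA_real_, 4L))
    dat <- dat[seq_len(n)]
    dat[dat == "."] <- NA_character_
    v <- as.numeric(dat)
    tri <- if (n >= 6L && eye == "right") v[4:6] else v[1:3]
    c(as.numeric(tk[1L]), tri)
  }
  m <- t(vapply(toks, parse_one, numeric(4)))
  bad <- is.na(m[, 1L])
  out <- data.frame(trackertime = m[!bad, 1L], x = m[!bad, 2L],
                    y = m[!bad, 3L], pp = m[!bad, 4L])
  out <- out[order(out$trackertime), , drop = FALSE]
  list(data = out, n_skipped = sum(bad))
}

# EFIX L <start> <end> <dur> <x> <y> <pp>
# ESACC L <start> <end> <dur> <sx> <sy> <ex> <ey> [<amp> [<vel>]]
# EBLINK L <start> <end> <dur>
parse_event_lines <- function(lines) {
  empty <- data.frame(kind = character(0), start_time = numeric(0),
                      end_time = numeric(0), duration = numeric(0),
                      x = numeric(0), y = numeric(0), pp = numeric(0),
                      end_x = numeric(0), end_y = numeric(0),
                      amplitude = numeric(0))
  if (!length(lines)) return(empty)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(tk) {
    kind <- switch(tk[1L], EFIX = "fixation", ESACC = "saccade",
                   EBLINK = "blink")
    num <- function(i) if (length(tk) >= i && tk[i] != ".")
      suppressWarnings(as.numeric(tk[i])) else NA_real_
    st <- num(3L); en <- num(4L)
    out <- data.frame(kind = kind, start_time = st, end_time = en,
                      duration = en - st, x = NA_real_, y = NA_real_,
                      pp = NA_real_, end_x = NA_real_, end_y = NA_real_,
                      amplitude = NA_real_)
    if (kind == "fixation") {
      out$x <- num(6L); out$y <- num(7L); out$pp <- num(8L)
    } else if (kind == "saccade") {
      out$x <- num(6L); out$y <- num(7L)
      out$end_x <- num(8L); out$end_y <- num(9L); out$amplitude <- num(10L)
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$start_time) & !is.na(out$end_time), , drop = FALSE]
  out[order(out$start_time), , drop = FALSE]
}

# Walk conforming messages in time order, pairing starts with stops.
# A start while a trial is open drops the open trial (nested/interleaved
# boundaries are rejected, not guessed at); a stop with no open trial is
# ignored with a warning; a start left open at end of file is dropped.
segment_trials <- function(mk, spec) {
  out <- data.frame(start_time = numeric(0), stop_time = numeric(0),
                    start_msg = character(0), stop_msg = character(0))
  open_i <- NA_integer_
  for (i in seq_len(nrow(mk))) {
    txt <- mk$text[i]
    if (is_boundary(txt, spec$start_message, spec)) {
      if (!is.na(open_i))
        warnf("trial opened by %s at %s has no stop before the next start; dropped",
              dQuote(mk$text[open_i]), format(mk$time[open_i]))
      open_i <- i
    } else if (is_boundary(txt, spec$stop_message, spec)) {
      if (is.na(open_i)) {
        warnf("stop message %s at %s has no open trial; ignored",
              dQuote(txt), format(mk$time[i]))
      } else {
        out <- rbind(out, data.frame(
          start_time = mk$time[open_i], stop_time = mk$time[i],
          start_msg = mk$text[open_i], stop_msg = txt))
        open_i <- NA_integer_
      }
    }
  }
  if (!is.na(open_i))
    warnf("trial opened by %s at %s is unmatched at end of file; dropped",
          dQuote(mk$text[open_i]), format(mk$time[open_i]))
  out
}

parsed_fields_for <- function(texts, spec) {
  parsed <- lapply(texts, parse_marker, spec = spec)
  out <- list()
  for (fn in spec$field_names)
    out[[fn]] <- unlist(lapply(parsed, `[[`, fn), use.names = FALSE)
  out
}

empty_samples <- function(spec) {
  out <- data.frame(trialtime = numeric(0), trackertime = numeric(0),
                    x = numeric(0), y = numeric(0), pp = numeric(0),
                    msg = character(0), msgtime = numeric(0))
  for (fn in spec$field_names) out[[fn]] <- character(0)
  out
}

empty_events <- function(spec) {
  out <- parse_event_lines(character(0))
  for (fn in spec$field_names) out[[fn]] <- character(0)
  out
}

#' Read and combine recordings from several participants
#'
#' Applies [read_asc()] to each path and row-binds the sample tables with a
#' participant identifier column.
#'
#' @param paths character vector of ASC paths (at least one).
#' @param spec a [marker_spec()].
#' @param id_from function mapping a path to a participant id; defaults to
#'   the file name without extension.
#' @param id_col name of the participant column.
#' @inheritParams read_asc
#' @return a single sample data.frame with an added participant column.
#' @export
read_many <- function(paths, spec,
                      id_from = function(p) tools::file_path_sans_ext(basename(p)),
                      id_col = "participant", eye = c("left", "right")) {
  if (length(paths) == 0L) stopf("'paths' must contain at least one path")
  eye <- match.arg(eye)
  tabs <- lapply(paths, function(p) {
    s <- read_asc(p, spec, eye = eye)$samples
    s[[id_col]] <- id_from(p)
    s
  })
  schemas <- lapply(tabs, names)
  ref <- schemas[[1L]]
  for (i in seq_along(schemas)) {
    if (!identical(schemas[[i]], ref)) {
      off <- union(setdiff(schemas[[i]], ref), setdiff(ref, schemas[[i]]))
      stopf("column schema of %s differs from %s (offending: %s)",
            paths[i], paths[1L], paste(off, collapse = ", "))
    }
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Validate a generic sample table into the canonical schema
#'
#' Accepts any long-format eye-tracking table and maps its columns onto the
#' canonical roles (trial identifiers, time, x, y, pupil). Mapped columns
#' are renamed to `trackertime`, `x`, `y`, `pp`; identifier columns keep
#' their names; `trialtime` is computed per trial. Time must be strictly
#' increasing within every trial.
#'
#' @param table a data.frame of samples.
#' @param column_map named list with entries `trial` (character vector of
#'   one or more identifier columns), `time`, `x`, `y`, `pupil`.
#' @return the canonicalised data.frame, with attribute `"trial_identifier"`.
#' @export
validate_generic <- function(table, column_map) {
  roles <- c("trial", "time", "x", "y", "pupil")
  for (r in roles)
    if (is.null(column_map[[r]])) stopf("role '%s' unmapped", r)
  need <- unlist(column_map[roles], use.names = FALSE)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stopf("mapped column(s) absent from table: %s",
          paste(missing_cols, collapse = ", "))
  id_cols <- column_map$trial
  out <- table
  ren <- c(time = "trackertime", x = "x", y = "y", pupil = "pp")
  for (r in names(ren)) {
    src <- column_map[[r]]
    if (!identical(src, ren[[r]])) {
      if (ren[[r]] %in% names(out) && ren[[r]] != src)
        stopf("cannot rename '%s' to '%s': column already exists", src, ren[[r]])
      names(out)[names(out) == src] <- ren[[r]]
    }
  }
  groups <- trial_row_groups(out, id_cols)
  out$trialtime <- NA_real_
  for (key in names(groups)) {
    rows <- groups[[key]]
    tt <- out$trackertime[rows]
    if (anyDuplicated(tt))
      stopf("duplicate timestamps within trial %s", key)
    if (is.unsorted(tt, strictly = TRUE))
      stopf("time not strictly increasing within trial %s", key)
    out$trialtime[rows] <- tt - tt[1L]
  }
  attr(out, "trial_identifier") <- id_cols
  out
}
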