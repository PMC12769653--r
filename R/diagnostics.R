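# Diagnostics: robust outlier flags for baselines and whole traces, the
# per-trial preprocessing summary, trial validation, and the grid behind
# the pupil-foreshortening surface plot. All flags are advisory — they
# never modify pupil columns; exclusion happens only through
# validate_trials().

#' Flag baseline outliers with a robust MAD band
#'
#' Baselines outside `[median - n * MAD, median + n * MAD]` (raw MAD,
#' inclusive bounds — so identical values are never flagged) are marked as
#' suspected outliers. With `group_by`, the band is computed within each
#' group independently (e.g. per participant). Flags are suggestions only;
#' distorted baselines propagate multiplicatively through baseline-corrected
#' analyses, so they deserve inspection rather than blind exclusion.
#'
#' @param baselines a data.frame containing a `baseline` column plus trial
#'   identifier columns (e.g. the step record of [baseline_correct()]), or
#'   a bare numeric vector.
#' @param n band multiplier (default 4).
#' @param group_by optional character vector of grouping columns.
#' @param value_col name of the value column (default `"baseline"`).
#' @return an object of class `outlier_report`: a list with `flags` (the
#'   input frame plus a logical `outlier` column), `thresholds` (per group:
#'   lower/upper) and `n`.
#' @export
check_baseline_outliers <- function(baselines, n = 4, group_by = NULL,
                                    value_col = "baseline") {
  if (is.numeric(baselines) && is.null(dim(baselines))) {
    baselines <- data.frame(trial = seq_along(baselines),
                            baseline = as.numeric(baselines))
    value_col <- "baseline"
  }
  stopifnot(is.data.frame(baselines), value_col %in% names(baselines))
  df <- baselines
  grp <- if (is.null(group_by)) rep("all", nrow(df))
         else trial_key(df, group_by)
  df$outlier <- NA
  thr <- data.frame(group = character(0), lower = numeric(0),
                    upper = numeric(0))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    v <- df[[value_col]][rows]
    if (all(is.na(v))) {
      warnf("group %s has no baseline values; omitted", g)
      next
    }
    med <- stats::median(v, na.rm = TRUE)
    m <- mad_raw(v)
    lo <- med - n * m; hi <- med + n * m
    df$outlier[rows] <- !is.na(v) & (v < lo | v > hi)
    thr <- rbind(thr, data.frame(group = g, lower = lo, upper = hi))
  }
  structure(list(kind = "baseline", flags = df, thresholds = thr, n = n,
                 group_by = group_by, value_col = value_col),
            class = "outlier_report")
}

#' Flag outlier pupil traces against the grand mean
#'
#' Aligns all trial traces on the trial clock, computes the pointwise grand
#' mean over trials at every time point (missing ignored), and for each
#' trial the maximum absolute distance from that mean,
#' `D_j = max_t |p_j(t) - mean(t)|`. The band half-width is
#' `median(D) + n * MAD(D)` (raw MAD); a trial is flagged when its trace
#' exits `mean(t) +/- half-width` anywhere — i.e. when `D_j` strictly
#' exceeds the half-width. Identical traces give a zero-width band and no
#' flags. Trials with no non-missing sample on the common grid cannot be
#' evaluated and are reported separately.
#'
#' @param state a [pupil_processor()].
#' @param n band multiplier (default 4).
#' @param column pupil column to assess; defaults to the latest stage.
#' @return an `outlier_report` with per-trial `max_dev`, the band
#'   half-width, the grand-mean trace, and `unevaluable` trial keys.
#' @export
check_trace_outliers <- function(state, n = 4,
                                 column = latest_column(state)) {
  stopifnot(inherits(state, "pupil_processor"))
  tcol <- state$time_col
  groups <- trial_row_groups(state$data, state$trial_identifier)
  if (length(groups) < 2L)
    stopf("need at least 2 trials for trace outlier detection")
  times <- sort(unique(state$data[[tcol]]))
  tmap <- match(state$data[[tcol]], times)
  vals <- state$data[[column]]
  ok <- !is.na(vals)
  agg <- tapply(vals[ok], tmap[ok], sum)
  cnt <- tapply(vals[ok], tmap[ok], length)
  gm <- rep(NA_real_, length(times))
  gm[as.integer(names(agg))] <- as.numeric(agg) / as.numeric(cnt)
  dev <- numeric(length(groups)); names(dev) <- names(groups)
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    d <- abs(vals[rows] - gm[tmap[rows]])
    dev[gi] <- if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
  }
  uneval <- names(dev)[is.na(dev)]
  dv <- dev[!is.na(dev)]
  half <- stats::median(dv) + n * mad_raw(dv)
  ids <- trial_index(state$data, state$trial_identifier)
  flags <- cbind(ids, data.frame(max_dev = as.numeric(dev),
                                 outlier = !is.na(dev) & dev > half))
  structure(list(kind = "trace", flags = flags,
                 half_width = half, grand_mean = gm, times = times,
                 unevaluable = uneval, n = n, column = column),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report:%s> %d unit(s), %d flagged (n = %g)\n",
              x$kind, nrow(x$flags), sum(x$flags$outlier, na.rm = TRUE), x$n))
  invisible(x)
}

#' Per-trial preprocessing summary
#'
#' One row per trial aggregating every step record — missing proportions
#' before/after each step, success flags, the interpolated flag, the
#' stored baseline — plus outlier flags from any [check_baseline_outliers()]
#' or [check_trace_outliers()] reports supplied. The numeric columns are
#' intended for building refined exclusion criteria by ordinary subsetting.
#'
#' @param object a [pupil_processor()].
#' @param reports optional list of `outlier_report` objects to merge in.
#' @param ... unused.
#' @return a data.frame, one row per trial.
#' @export
summary.pupil_processor <- function(object, reports = NULL, ...) {
  state <- object
  ids <- trial_index(state$data, state$trial_identifier)
  keys <- attr(ids, "keys")
  out <- ids
  n_per_trial <- vapply(trial_row_groups(state$data, state$trial_identifier),
                        length, integer(1))
  out$n_samples <- as.integer(n_per_trial)
  for (s in state$steps) {
    st <- s$stats
    skeys <- trial_key(st, state$trial_identifier)
    m <- match(keys, skeys)
    pref <- s$name
    out[[paste0(pref, "_prop_missing")]] <-
      st$n_missing_after[m] / out$n_samples
    out[[paste0(pref, "_ok")]] <- st$succeeded[m]
    if (!is.null(st$interpolated))
      out$interpolated <- st$interpolated[m]
    if (!is.null(st$baseline))
      out$baseline <- st$baseline[m]
  }
  for (rep in reports %||% list()) {
    stopifnot(inherits(rep, "outlier_report"))
    fl <- rep$flags
    if (all(state$trial_identifier %in% names(fl))) {
      m <- match(keys, trial_key(fl, state$trial_identifier))
      out[[paste0(rep$kind, "_outlier")]] <- fl$outlier[m]
      if (!is.null(fl$max_dev))
        out[[paste0(rep$kind, "_max_dev")]] <- fl$max_dev[m]
    }
  }
  rownames(out) <- NULL
  out
}

#' Mark trials as invalid
#'
#' Adds (or replaces) a logical `valid` column on the sample table: `FALSE`
#' for every sample of the listed trials, `TRUE` otherwise. Idempotent.
#' Exclusion is entirely user-driven: outlier reports are suggestions, and
#' only this function ever writes validity.
#'
#' @param state a [pupil_processor()].
#' @param invalid data.frame of trial identifier tuples to exclude (a
#'   subset of the columns in `trial_identifier`... all must be present);
#'   zero rows marks everything valid.
#' @return the updated processor. Tuples that match no trial produce a
#'   warning listing them.
#' @export
validate_trials <- function(state, invalid) {
  stopifnot(inherits(state, "pupil_processor"), is.data.frame(invalid))
  idc <- state$trial_identifier
  if (!all(idc %in% names(invalid)) && nrow(invalid) > 0)
    stopf("'invalid' must carry the identifier column(s): %s",
          paste(idc, collapse = ", "))
  keys <- trial_key(state$data, idc)
  bad_keys <- if (nrow(invalid)) unique(trial_key(invalid, idc)) else character(0)
  unmatched <- setdiff(bad_keys, unique(keys))
  if (length(unmatched))
    warnf("identifier tuple(s) not present in data: %s",
          paste(unmatched, collapse = "; "))
  state$data$valid <- !(keys %in% bad_keys)
  state
}

#' Gaze-position surface of sample counts or mean pupil size
#'
#' Bins samples on a 2D gaze grid. In `"count"` mode each cell holds the
#' number of samples recorded there (a 2D histogram of gaze, revealing the
#' spatial spread and hence the scope for pupil foreshortening error); in
#' `"size"` mode each cell holds the mean pupil size, which makes
#' foreshortening visible as a radial gradient. Also returns the overall
#' mean gaze position across non-missing samples.
#'
#' @param state a [pupil_processor()].
#' @param bins `c(nx, ny)` cell counts.
#' @param mode `"count"` or `"size"`.
#' @param column pupil column for `"size"` mode; defaults to the latest
#'   stage column.
#' @param xlim,ylim grid extents; default to the data range.
#' @return list with `grid` (ny x nx matrix, row 1 = smallest y),
#'   `x_breaks`, `y_breaks`, `mean_gaze` (c(x, y)) and `mode`.
#' @export
pupil_surface <- function(state, bins = c(64, 36),
                          mode = c("count", "size"),
                          column = latest_column(state),
                          xlim = NULL, ylim = NULL) {
  stopifnot(inherits(state, "pupil_processor"))
  mode <- match.arg(mode)
  x <- state$data[[state$x_col]]; y <- state$data[[state$y_col]]
  keep <- !is.na(x) & !is.na(y)
  if (mode == "size") {
    p <- state$data[[column]]
    keep <- keep & !is.na(p)
  }
  if (!any(keep)) stopf("no non-missing samples to bin")
  x <- x[keep]; y <- y[keep]
  xlim <- xlim %||% range(x); ylim <- ylim %||% range(y)
  if (diff(xlim) == 0) xlim <- xlim + c(-0.5, 0.5)   # all-constant gaze
  if (diff(ylim) == 0) ylim <- ylim + c(-0.5, 0.5)
  xb <- seq(xlim[1], xlim[2], length.out = bins[1] + 1L)
  yb <- seq(ylim[1], ylim[2], length.out = bins[2] + 1L)
  xi <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1L), bins[1])
  yi <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1L), bins[2])
  grid <- matrix(0, nrow = bins[2], ncol = bins[1])
  if (mode == "count") {
    tab <- table(factor(yi, levels = seq_len(bins[2])),
                 factor(xi, levels = seq_len(bins[1])))
    grid[] <- as.numeric(tab)
  } else {
    p <- state$data[[column]][keep]
    cell <- (xi - 1L) * bins[2] + yi
    s <- tapply(p, cell, mean)
    grid[as.integer(names(s))] <- as.numeric(s)
    grid[setdiff(seq_len(bins[1] * bins[2]), as.integer(names(s)))] <- NA
  }
  list(grid = grid, x_breaks = xb, y_breaks = yb,
       mean_gaze = c(mean(x), mean(y)), mode = mode)
}
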