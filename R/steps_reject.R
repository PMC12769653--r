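# Artifact rejection: a robust speed threshold (dilation speed outliers)
# and a z-score rule guarded by a coefficient-of-variation check.

#' Speed-based artifact mask for one trace
#'
#' Computes the pupil dilation speed at every sample as the absolute
#' maximum of the forward and backward first differences, each normalised
#' by its time difference; endpoints use their single available side.
#' The rejection threshold is `median(speed) + n * MAD(speed)` with the raw
#' (unscaled) median absolute deviation, and a sample is rejected only when
#' its speed strictly exceeds the threshold — so a constant or perfectly
#' linear trace (MAD 0) rejects nothing. Differences are taken between
#' consecutive non-missing samples, so gaps contribute a speed across the
#' gap rather than propagating `NA`.
#'
#' @param trace numeric pupil series of one trial.
#' @param times sample times in ms.
#' @param n threshold multiplier (default 16).
#' @return logical mask, `TRUE` where the sample is rejected; missing
#'   samples are always `FALSE`. Fewer than 3 non-missing samples give an
#'   all-`FALSE` mask with attribute `"failed" = TRUE`.
#' @export
reject_speed <- function(trace, times, n = 16) {
  stopifnot(length(trace) == length(times))
  mask <- rep(FALSE, length(trace))
  ok <- which(!is.na(trace))
  if (length(ok) < 3L) {
    attr(mask, "failed") <- TRUE
    return(mask)
  }
  p <- trace[ok]; t <- times[ok]
  fwd <- c(abs(diff(p)) / diff(t), NA)   # speed toward the next sample
  bwd <- c(NA, abs(diff(p)) / diff(t))   # speed from the previous sample
  d <- pmax(fwd, bwd, na.rm = TRUE)
  thr <- stats::median(d) + n * mad_raw(d)
  mask[ok[d > thr]] <- TRUE
  attr(mask, "threshold") <- thr
  mask
}

#' Z-score artifact mask guarded by the coefficient of variation
#'
#' Rejects samples whose within-trial z-score exceeds `z_threshold` in
#' absolute value — but only when the trace's coefficient of variation
#' (sd/mean) exceeds `cv_threshold`; traces at or below it are returned
#' untouched, which protects stable data from being chipped away. Both
#' statistics use the non-missing samples of the trace.
#'
#' @param trace numeric pupil series of one trial.
#' @param z_threshold z-score cutoff (default 2.5).
#' @param cv_threshold coefficient-of-variation guard (default 0.1).
#' @return logical mask as in [reject_speed()]; a zero mean (CV undefined)
#'   gives an all-`FALSE` mask with attribute `"failed" = TRUE`.
#' @export
reject_zscore <- function(trace, z_threshold = 2.5, cv_threshold = 0.1) {
  mask <- rep(FALSE, length(trace))
  ok <- which(!is.na(trace))
  if (length(ok) < 2L) {
    attr(mask, "failed") <- TRUE
    return(mask)
  }
  p <- trace[ok]
  m <- mean(p)
  if (m == 0) {
    attr(mask, "failed") <- TRUE
    return(mask)
  }
  s <- stats::sd(p)
  cv <- s / m
  attr(mask, "cv") <- cv
  if (is.na(cv) || cv <= cv_threshold || s == 0) return(mask)
  z <- (p - m) / s
  mask[ok[abs(z) > z_threshold]] <- TRUE
  mask
}

#' Reject pupil-size artifacts
#'
#' Applies the speed and/or z-score rule per trial to the latest stage
#' column and writes `<input>_ar` with rejected samples set missing. With
#' `method = "both"` (the default) the two masks are computed on the same
#' input column and their union is applied, so the result does not depend
#' on an ordering of the two rules.
#'
#' @param state a [pupil_processor()].
#' @param method `"speed"`, `"zscore"` or `"both"`.
#' @param n_speed speed-threshold multiplier (default 16).
#' @param z_threshold,cv_threshold z-score rule parameters.
#' @return the updated processor.
#' @export
artifact_rejection <- function(state, method = c("both", "speed", "zscore"),
                               n_speed = 16, z_threshold = 2.5,
                               cv_threshold = 0.1) {
  stopifnot(inherits(state, "pupil_processor"))
  method <- match.arg(method)
  input <- latest_column(state)
  output <- stage_output(state, "ar")
  tcol <- state$time_col
  res <- map_trials(state, function(x, rows, key) {
    tms <- state$data[[tcol]][rows]
    msk <- rep(FALSE, length(x))
    failed <- FALSE
    thr <- NA_real_
    if (method %in% c("both", "speed")) {
      ms <- reject_speed(x, tms, n = n_speed)
      failed <- failed || isTRUE(attr(ms, "failed"))
      thr <- attr(ms, "threshold") %||% NA_real_
      msk <- msk | ms
    }
    if (method %in% c("both", "zscore")) {
      mz <- reject_zscore(x, z_threshold, cv_threshold)
      failed <- failed || isTRUE(attr(mz, "failed"))
      msk <- msk | mz
    }
    v <- x
    v[msk] <- NA_real_
    list(values = v,
         stats = list(n_missing_before = sum(is.na(x)),
                      n_missing_after = sum(is.na(v)),
                      succeeded = !failed,
                      n_rejected = sum(msk),
                      speed_threshold = thr))
  }, input = input)
  state$data[[output]] <- res$values
  add_step(state, "artifact_rejection", "ar", input, output,
           list(method = method, n_speed = n_speed,
                z_threshold = z_threshold, cv_threshold = cv_threshold),
           res$stats)
}

#' Define a valid gaze region
#'
#' Either an axis-aligned rectangle in screen pixels or a closed polygon.
#' Boundary points count as inside.
#'
#' @param x_min,x_max,y_min,y_max rectangle bounds (pixels, origin top-left).
#' @param polygon alternatively, a closed two-column vertex matrix (first
#'   vertex repeated last); must not self-intersect.
#' @return an object of class `valid_region`.
#' @export
valid_region <- function(x_min = NULL, x_max = NULL, y_min = NULL,
                         y_max = NULL, polygon = NULL) {
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    check_closed_polygon(polygon, "valid region")
    if (polygon_area(polygon) == 0)
      stopf("valid region polygon has zero area")
    return(structure(list(shape = "polygon", polygon = polygon),
                     class = "valid_region"))
  }
  stopifnot(!is.null(x_min), !is.null(x_max), !is.null(y_min), !is.null(y_max))
  if (!(x_min < x_max && y_min < y_max))
    stopf("degenerate rectangle: need x_min < x_max and y_min < y_max")
  structure(list(shape = "rectangle", x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max),
            class = "valid_region")
}

region_contains <- function(region, x, y) {
  if (region$shape == "rectangle") {
    x >= region$x_min & x <= region$x_max &
      y >= region$y_min & y <= region$y_max
  } else {
    vapply(seq_along(x), function(i)
      point_in_polygon(c(x[i], y[i]), region$polygon), logical(1))
  }
}

#' Set pupil samples outside a valid gaze region to missing
#'
#' Pupil size is distorted when the eye rotates away from the camera
#' (pupil foreshortening), so samples recorded while gaze was outside a
#' declared region are untrustworthy. Writes `<input>_xy` with the pupil
#' set missing wherever (x, y) falls outside `region` or x/y are themselves
#' missing. Points exactly on the region boundary are kept.
#'
#' @param state a [pupil_processor()].
#' @param region a [valid_region()].
#' @return the updated processor.
#' @export
filter_position <- function(state, region) {
  stopifnot(inherits(state, "pupil_processor"),
            inherits(region, "valid_region"))
  input <- latest_column(state)
  output <- stage_output(state, "xy")
  xcol <- state$x_col; ycol <- state$y_col
  res <- map_trials(state, function(p, rows, key) {
    x <- state$data[[xcol]][rows]; y <- state$data[[ycol]][rows]
    bad <- is.na(x) | is.na(y)
    inside <- rep(FALSE, length(x))
    inside[!bad] <- region_contains(region, x[!bad], y[!bad])
    v <- p
    v[!inside] <- NA_real_
    list(values = v,
         stats = list(n_missing_before = sum(is.na(p)),
                      n_missing_after = sum(is.na(v)),
                      succeeded = TRUE,
                      n_outside = sum(!inside & !is.na(p))))
  }, input = input)
  state$data[[output]] <- res$values
  add_step(state, "filter_position", "xy", input, output,
           list(region = region), res$stats)
}
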