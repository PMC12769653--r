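# Static figure exports for the diagnostic computations. Interactivity
# (hover, zoom, trial dropdowns) is out of scope; these render the same
# quantities to PNG/SVG/PDF files chosen by extension.

open_device <- function(file, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = grDevices::png(file, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(file, width = width, height = height),
    pdf = grDevices::pdf(file, width = width, height = height),
    stopf("unsupported figure extension '.%s' (use png, svg or pdf)", ext))
}

# Pick a figure extension that the running R build can actually render.
default_fig_ext <- function() {
  if (capabilities("png")) "png" else "pdf"
}

#' Plot the gaze-position surface
#'
#' Renders a [pupil_surface()] grid as an image with a cross at the mean
#' gaze position, and writes it to `file`. The y axis is drawn increasing
#' downward to match screen coordinates.
#'
#' @param surface result of [pupil_surface()].
#' @param file output path (`.png`, `.svg` or `.pdf`).
#' @return `file`, invisibly.
#' @export
plot_pupil_surface <- function(surface, file) {
  open_device(file, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  xb <- surface$x_breaks; yb <- surface$y_breaks
  g <- t(surface$grid)
  graphics::image(x = xb, y = yb, z = g,
                  col = grDevices::hcl.colors(64, "viridis"),
                  ylim = rev(range(yb)), xlab = "x (px)", ylab = "y (px)",
                  main = sprintf("Gaze surface (%s)", surface$mode),
                  useRaster = TRUE)
  graphics::points(surface$mean_gaze[1], surface$mean_gaze[2],
                   pch = 3, col = "red", cex = 2, lwd = 2)
  invisible(file)
}

#' Plot the baseline histogram with outlier thresholds
#'
#' Histogram of per-trial baselines (Freedman-Diaconis binning) with the
#' robust band of a [check_baseline_outliers()] report drawn as dashed
#' lines, one panel per group.
#'
#' @param report a baseline `outlier_report`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
plot_baseline_histogram <- function(report, file) {
  stopifnot(inherits(report, "outlier_report"), report$kind == "baseline")
  groups <- report$thresholds$group
  open_device(file, width = 6, height = 4 * max(1, length(groups)))
  on.exit(grDevices::dev.off(), add = TRUE)
  if (length(groups) > 1L)
    graphics::par(mfrow = c(length(groups), 1))
  fl <- report$flags
  grp <- if (is.null(report$group_by)) rep("all", nrow(fl))
         else trial_key(fl, report$group_by)
  for (g in groups) {
    v <- fl[[report$value_col]][grp == g]
    v <- v[!is.na(v)]
    graphics::hist(v, breaks = "FD", col = "grey80", border = "white",
                   xlab = "baseline pupil size", main = paste("group", g))
    th <- report$thresholds[report$thresholds$group == g, ]
    graphics::abline(v = c(th$lower, th$upper), lty = 2, col = "red")
  }
  invisible(file)
}

#' Plot the trace spaghetti with the robust band
#'
#' All trial traces against trial time, the grand-mean trace, and the
#' constant-width robust band of a [check_trace_outliers()] report as
#' dashed lines; flagged traces are drawn in red.
#'
#' @param state a [pupil_processor()].
#' @param report a trace `outlier_report` produced from `state`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
plot_trace_spaghetti <- function(state, report, file) {
  stopifnot(inherits(report, "outlier_report"), report$kind == "trace")
  open_device(file, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  tcol <- state$time_col
  vals <- state$data[[report$column]]
  rng <- range(c(vals, report$grand_mean + report$half_width,
                 report$grand_mean - report$half_width), na.rm = TRUE)
  graphics::plot(NA, xlim = range(report$times), ylim = rng,
                 xlab = "trial time (ms)", ylab = report$column,
                 main = "Pupil traces")
  groups <- trial_row_groups(state$data, state$trial_identifier)
  flagged <- trial_key(report$flags, state$trial_identifier)[report$flags$outlier]
  for (key in names(groups)) {
    rows <- groups[[key]]
    graphics::lines(state$data[[tcol]][rows], vals[rows],
                    col = if (key %in% flagged) "red"
                          else grDevices::adjustcolor("grey40", 0.5))
  }
  graphics::lines(report$times, report$grand_mean, col = "blue", lwd = 2)
  graphics::lines(report$times, report$grand_mean + report$half_width,
                  lty = 2, col = "blue")
  graphics::lines(report$times, report$grand_mean - report$half_width,
                  lty = 2, col = "blue")
  invisible(file)
}
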