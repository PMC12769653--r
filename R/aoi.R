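# Areas of interest: closed-polygon regions on the screen used to
# aggregate fixation metrics. An AOI set is a named list of closed vertex
# matrices, optionally nested one level deep per trial key.

check_closed_polygon <- function(poly, name) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 4L)
    stopf("AOI '%s': a closed polygon needs >= 4 two-column vertices (first repeated last)",
          name)
  if (!isTRUE(all.equal(poly[1L, ], poly[nrow(poly), ], check.attributes = FALSE)))
    stopf("AOI '%s': polygon is not closed (last vertex must repeat the first)",
          name)
  invisible(poly)
}

polygon_area <- function(poly) {
  n <- nrow(poly) - 1L
  x <- poly[1:n, 1]; y <- poly[1:n, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# TRUE if segments a1-a2 and b1-b2 properly intersect (interiors cross).
segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

check_simple_polygon <- function(poly, name) {
  n <- nrow(poly) - 1L
  if (n < 3L) return(invisible(poly))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j > i + 1L && !(i == 1L && j == n))
        if (segments_cross(poly[i, ], poly[i + 1L, ], poly[j, ], poly[j + 1L, ]))
          stopf("polygon '%s' self-intersects (edges %d and %d)", name, i, j)
  invisible(poly)
}

#' Build and validate an AOI set
#'
#' Flat form: a named list mapping each AOI name to a closed polygon — a
#' two-column vertex matrix (or list of `c(x, y)` pairs) whose last vertex
#' repeats the first. Nested form: a named list of such sets keyed by trial
#' (identifier tuples joined by `"|"`), for designs where the regions move
#' between trials.
#'
#' @param x the (possibly nested) named list of polygons.
#' @return an object of class `aoi_set` with attribute `nested`.
#' @export
aoi_set <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  as_poly <- function(v) {
    m <- if (is.matrix(v)) v else do.call(rbind, lapply(v, as.numeric))
    storage.mode(m) <- "double"
    unname(m)
  }
  # a flat value is a polygon: a matrix, or a list of length-2 coordinate
  # pairs; a nested value is a named list of polygons
  is_polygon_like <- function(v) {
    is.matrix(v) || (is.list(v) && length(v) > 0L &&
      all(vapply(v, function(p)
        (is.numeric(p) || is.list(p)) && length(p) == 2L &&
          all(vapply(as.list(p), is.numeric, logical(1))), logical(1))))
  }
  nested <- length(x) > 0L && !any(vapply(x, is_polygon_like, logical(1)))
  if (nested) {
    out <- lapply(x, function(level) {
      if (anyDuplicated(names(level)))
        stopf("duplicate AOI names within a trial level")
      polys <- lapply(names(level), function(nm) {
        p <- as_poly(level[[nm]])
        check_closed_polygon(p, nm)
        check_simple_polygon(p, nm)
        p
      })
      names(polys) <- names(level)
      polys
    })
  } else {
    if (anyDuplicated(names(x))) stopf("duplicate AOI names")
    out <- lapply(names(x), function(nm) {
      p <- as_poly(x[[nm]])
      check_closed_polygon(p, nm)
      check_simple_polygon(p, nm)
      p
    })
    names(out) <- names(x)
  }
  structure(out, class = "aoi_set", nested = nested)
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' @param point numeric `c(x, y)`.
#' @param polygon closed vertex matrix (first row repeated last).
#' @param eps tolerance for the boundary test.
#' @return `TRUE` iff the point is strictly inside or on the boundary.
#' @export
point_in_polygon <- function(point, polygon, eps = 1e-9) {
  polygon <- as.matrix(polygon)
  if (!isTRUE(all.equal(polygon[1L, ], polygon[nrow(polygon), ],
                        check.attributes = FALSE)))
    stopf("polygon is open: the last vertex must repeat the first")
  px <- point[1]; py <- point[2]
  n <- nrow(polygon) - 1L
  xs <- polygon[, 1]; ys <- polygon[, 2]
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1L]; y2 <- ys[i + 1L]
    # boundary: point collinear with and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (abs(cross) <= eps * max(1, sqrt(seg_len2)) &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps)
      return(TRUE)
    # even-odd ray cast toward +x
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Assign each fixation to an AOI
#'
#' Labels every fixation with the first AOI (in declaration order) whose
#' polygon contains its (x, y), or `"outside"` when none does. Boundary
#' points count as inside; declaration order resolves overlaps
#' deterministically. With a nested AOI set, each fixation's trial key
#' (identifier columns joined by `"|"`) selects the per-trial AOIs.
#'
#' @param fixations data.frame with `x`, `y` and, for nested sets, the
#'   trial identifier columns.
#' @param aois an [aoi_set()].
#' @param trial_identifier identifier columns used to build trial keys for
#'   nested sets.
#' @param aoi_col name of the label column added (default `"aoi"`).
#' @return `fixations` with the label column added.
#' @export
assign_aoi <- function(fixations, aois, trial_identifier = NULL,
                       aoi_col = "aoi") {
  stopifnot(is.data.frame(fixations), inherits(aois, "aoi_set"))
  nested <- isTRUE(attr(aois, "nested"))
  if (nested && is.null(trial_identifier))
    stopf("nested AOIs need 'trial_identifier' to resolve trial keys")
  keys <- if (nested) trial_key(fixations, trial_identifier) else NULL
  label_one <- function(x, y, polys) {
    for (nm in names(polys))
      if (point_in_polygon(c(x, y), polys[[nm]])) return(nm)
    "outside"
  }
  lab <- character(nrow(fixations))
  for (i in seq_len(nrow(fixations))) {
    polys <- if (nested) {
      if (is.null(aois[[keys[i]]]))
        stopf("no AOIs defined for trial key '%s'", keys[i])
      aois[[keys[i]]]
    } else aois
    lab[i] <- label_one(fixations$x[i], fixations$y[i], polys)
  }
  fixations[[aoi_col]] <- lab
  fixations
}

#' Per-trial, per-AOI fixation statistics
#'
#' Assigns fixations to AOIs and tabulates, for every combination of trial
#' and AOI name (including `"outside"` and zero-fixation combinations), the
#' fixation count and — when a duration column is present — the total
#' fixation duration.
#'
#' @inheritParams assign_aoi
#' @param duration_col duration column name, or `NULL` if absent.
#' @return data.frame with identifier columns, `aoi`, `n_fixations` and
#'   (if durations exist) `total_duration`.
#' @export
compute_aoi_statistics <- function(fixations, aois, trial_identifier,
                                   duration_col = "duration") {
  fx <- assign_aoi(fixations, aois, trial_identifier)
  nested <- isTRUE(attr(aois, "nested"))
  has_dur <- !is.null(duration_col) && duration_col %in% names(fixations)
  ids <- trial_index(fx, trial_identifier)
  keys <- attr(ids, "keys")
  fkeys <- trial_key(fx, trial_identifier)
  rows <- list()
  for (ki in seq_along(keys)) {
    polys <- if (nested) aois[[keys[ki]]] else aois
    names_all <- c(names(polys), "outside")
    sub <- fx[fkeys == keys[ki], , drop = FALSE]
    for (nm in names_all) {
      hit <- sub$aoi == nm
      row <- ids[ki, , drop = FALSE]
      row$aoi <- nm
      row$n_fixations <- sum(hit)
      if (has_dur)
        row$total_duration <- sum(sub[[duration_col]][hit])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixation density map
#'
#' Sum of isotropic Gaussian kernels centred on the fixations, evaluated on
#' the pixel grid of a canvas, weighted by fixation duration when present
#' (unit weight otherwise). For kernels well inside the canvas the grid
#' integral equals the total weight to within about 1%; kernels clipped by
#' the canvas edge lose the clipped mass.
#'
#' @param fixations data.frame with `x`, `y` and optionally a duration
#'   column.
#' @param canvas `c(width, height)` in pixels.
#' @param bandwidth Gaussian sd in pixels; default 2% of the canvas
#'   diagonal.
#' @param duration_col duration column used as weight, if present.
#' @return a `height x width` matrix (row 1 = y 0).
#' @export
fixation_density <- function(fixations, canvas, bandwidth = NULL,
                             duration_col = "duration") {
  stopifnot(length(canvas) == 2L, all(canvas > 0))
  w <- as.integer(canvas[1]); h <- as.integer(canvas[2])
  bandwidth <- bandwidth %||% (0.02 * sqrt(sum(canvas^2)))
  if (bandwidth <= 0) stopf("'bandwidth' must be positive")
  grid <- matrix(0, nrow = h, ncol = w)
  if (nrow(fixations) == 0L) return(grid)
  xs <- seq_len(w) - 1; ys <- seq_len(h) - 1
  wts <- if (!is.null(duration_col) && duration_col %in% names(fixations))
    fixations[[duration_col]] else rep(1, nrow(fixations))
  for (i in seq_len(nrow(fixations))) {
    gx <- stats::dnorm(xs, fixations$x[i], bandwidth)
    gy <- stats::dnorm(ys, fixations$y[i], bandwidth)
    grid <- grid + wts[i] * (gy %o% gx)
  }
  grid
}

#' Load / save AOI sets as JSON
#'
#' Flat files look like `{"name": [[x, y], ...]}`; nested files add one
#' level of trial keys: `{"A|1": {"name": [[x, y], ...]}}`. Round trips are
#' identity. Polygons are validated on load, so an unclosed polygon fails
#' with an error naming the AOI.
#'
#' @param path JSON file path.
#' @return for `load_aois`, an [aoi_set()].
#' @export
load_aois <- function(path) {
  if (!file.exists(path)) stopf("AOI file not found: %s", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stopf("malformed AOI JSON in %s: %s", path,
                          conditionMessage(e)))
  to_poly <- function(v) do.call(rbind, lapply(v, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  is_pair_list <- function(v) is.list(v) && length(v) > 0L &&
    all(vapply(v, function(p) (is.list(p) || is.numeric(p)) &&
                 length(p) == 2L, logical(1)))
  nested <- !is_pair_list(raw[[1]])
  if (nested) {
    out <- lapply(raw, function(level) lapply(level, to_poly))
  } else {
    out <- lapply(raw, to_poly)
  }
  aoi_set(out)
}

#' @rdname load_aois
#' @param aois an [aoi_set()].
#' @export
save_aois <- function(aois, path) {
  stopifnot(inherits(aois, "aoi_set"))
  nested <- isTRUE(attr(aois, "nested"))
  to_pairs <- function(m) lapply(seq_len(nrow(m)), function(i)
    c(m[i, 1], m[i, 2]))
  body <- if (nested) lapply(aois, function(level) lapply(level, to_pairs))
          else lapply(aois, to_pairs)
  jsonlite::write_json(body, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
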