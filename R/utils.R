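# Internal helpers shared across modules.

#' Raw median absolute deviation
#'
#' Median of absolute deviations from the median, without the 1.4826
#' consistency scaling. All robust thresholds in this package (speed
#' rejection, baseline and trace outlier bands) use this unscaled form,
#' following the Kret & Sjak-Shie convention for the n = 16 speed multiplier.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return a single number, the raw MAD.
#' @export
mad_raw <- function(x) {
  x <- x[!is.na(x)]
  stats::median(abs(x - stats::median(x)))
}

# Run-length encoding of a logical vector as (start, end) index pairs for
# the TRUE runs. Returns a data.frame with zero rows when there are none.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Paste identifier columns into a single key string ("A|4"). Used wherever
# trials must be matched across tables; "|" matches the nested-AOI JSON keys.
trial_key <- function(df, id_cols) {
  if (nrow(df) == 0L) return(character(0))
  do.call(paste, c(unname(as.list(df[id_cols])), list(sep = "|")))
}

# Unique trial identifier tuples, in first-appearance order.
trial_index <- function(df, id_cols) {
  keys <- trial_key(df, id_cols)
  idx <- !duplicated(keys)
  out <- df[idx, id_cols, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "keys") <- keys[idx]
  out
}

# split(seq_len(nrow(df)), key) preserving first-appearance trial order.
trial_row_groups <- function(df, id_cols) {
  keys <- trial_key(df, id_cols)
  split(seq_len(nrow(df)), factor(keys, levels = unique(keys)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
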