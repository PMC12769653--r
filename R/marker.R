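# Event-marker grammar: the user's declaration of how MSG strings written by
# the experiment script are structured, e.g. "start fixation A 4" =
# marker/event/block/trial with trial an integer.

#' Declare an event-marker grammar
#'
#' Experiments mark trial events by sending short text messages to the
#' recorder ("start fixation A 4"). A marker spec declares the ordered
#' fields of those messages, their types, the delimiter, and which message
#' prefixes open and close a trial. [read_asc()] uses the spec to segment a
#' recording into trials and to turn each message into typed columns.
#'
#' @param fields named character vector mapping field name to type, one of
#'   `"text"`, `"integer"`, `"decimal"`; order matters.
#' @param delimiter single non-empty token separating fields (default one
#'   space).
#' @param start_message message prefix that opens a trial, e.g.
#'   `"start fixation"`.
#' @param stop_message message prefix that closes a trial, e.g.
#'   `"end feedback"`.
#' @param constant_columns optional named list of constant values (e.g.
#'   participant id) appended to every parsed row.
#' @return an object of class `marker_spec`.
#' @examples
#' spec <- marker_spec(
#'   fields = c(marker = "text", event = "text", block = "text",
#'              trial = "integer"),
#'   start_message = "start fixation", stop_message = "end feedback")
#' parse_marker("start fixation A 4", spec)
#' @export
marker_spec <- function(fields,
                        delimiter = " ",
                        start_message,
                        stop_message,
                        constant_columns = NULL) {
  if (is.null(names(fields)) || any(!nzchar(names(fields))))
    stopf("'fields' must be a named vector of types")
  if (anyDuplicated(names(fields)))
    stopf("field names must be unique: %s",
          paste(unique(names(fields)[duplicated(names(fields))]), collapse = ", "))
  bad <- setdiff(unique(unname(fields)), c("text", "integer", "decimal"))
  if (length(bad))
    stopf("unknown field type(s): %s", paste(bad, collapse = ", "))
  if (!is.character(delimiter) || length(delimiter) != 1L || !nzchar(delimiter))
    stopf("'delimiter' must be a single non-empty string")
  spec <- structure(
    list(fields = unname(fields), field_names = names(fields),
         delimiter = delimiter,
         start_message = start_message, stop_message = stop_message,
         constant_columns = constant_columns),
    class = "marker_spec")
  for (msg in c(start_message, stop_message)) {
    ok <- tryCatch({parse_marker(msg, spec, partial = TRUE); TRUE},
                   error = function(e) FALSE)
    if (!ok) stopf("boundary message %s is not parseable under the declared fields",
                   dQuote(msg))
  }
  spec
}

#' Parse one event-marker message
#'
#' Splits `message` on the spec's delimiter and coerces each token to its
#' declared type.
#'
#' @param message a single message string.
#' @param spec a [marker_spec()].
#' @param partial if `TRUE`, accept messages with fewer tokens than declared
#'   fields (used to validate boundary prefixes, which typically omit the
#'   trailing dynamic fields); missing fields come back `NA`.
#' @return named list of typed values, one per declared field, in order.
#' @export
parse_marker <- function(message, spec, partial = FALSE) {
  stopifnot(inherits(spec, "marker_spec"), length(message) == 1L)
  toks <- strsplit(message, spec$delimiter, fixed = TRUE)[[1]]
  nf <- length(spec$fields)
  if (length(toks) != nf && !(partial && length(toks) <= nf))
    stopf("message %s has %d token(s) under delimiter %s but %d field(s) declared",
          dQuote(message), length(toks), dQuote(spec$delimiter), nf)
  out <- vector("list", nf)
  names(out) <- spec$field_names
  for (i in seq_len(nf)) {
    tok <- if (i <= length(toks)) toks[[i]] else NA_character_
    out[[i]] <- switch(spec$fields[[i]],
      text = tok,
      integer = {
        v <- suppressWarnings(as.integer(tok))
        if (!is.na(tok) && is.na(v))
          stopf("field '%s': token %s is not an integer (message %s)",
                spec$field_names[[i]], dQuote(tok), dQuote(message))
        v
      },
      decimal = {
        v <- suppressWarnings(as.numeric(tok))
        if (!is.na(tok) && is.na(v))
          stopf("field '%s': token %s is not a decimal (message %s)",
                spec$field_names[[i]], dQuote(tok), dQuote(message))
        v
      })
  }
  out
}

#' Format field values back into a message string
#'
#' Inverse of [parse_marker()] on well-formed inputs; used by the synthetic
#' recording generator.
#'
#' @param values named list of field values.
#' @param spec a [marker_spec()].
#' @return a single message string.
#' @export
format_marker <- function(values, spec) {
  stopifnot(inherits(spec, "marker_spec"))
  vals <- values[spec$field_names]
  paste(vapply(vals, function(v) format(v, scientific = FALSE, trim = TRUE),
               character(1)),
        collapse = spec$delimiter)
}

# TRUE when `message` opens (or closes) a trial: the boundary string must be
# a token-prefix of the message under the spec's delimiter.
is_boundary <- function(message, boundary, spec) {
  pre <- paste0(boundary, spec$delimiter)
  message == boundary | startsWith(message, pre)
}
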