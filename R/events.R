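#' Event series container
#'
#' An ordered set of event times on an observation interval \eqn{[0, T]},
#' optionally tagged by the id of the node (individual) that generated each
#' event.  This is the object the stationarity detector consumes and the
#' simulators produce.
#'
#' @param times numeric vector of event times; sorted internally.
#' @param T observation span; defaults to `max(times)` (0 for an empty
#'   series).
#' @param node_ids optional integer vector of per-event node tags, same
#'   length as `times`.
#' @return An object of class `event_series` with fields `times`, `T` and
#'   (optionally) `node_ids`.
#' @examples
#' es <- event_series(c(0.3, 1.2, 4.5), T = 10)
#' es
#' @export
event_series <- function(times, T = NULL, node_ids = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("event times must not contain NA", call. = FALSE)
  if (is.null(T)) T <- if (length(times)) max(times) else 0
  if (length(times) && (min(times) < 0 || max(times) > T))
    stop("event times must lie in [0, T]", call. = FALSE)
  ord <- order(times)
  times <- times[ord]
  if (!is.null(node_ids)) {
    if (length(node_ids) != length(times))
      stop("'node_ids' must match 'times' in length", call. = FALSE)
    node_ids <- as.integer(node_ids)[ord]
  }
  structure(list(times = times, T = as.numeric(T), node_ids = node_ids),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("Event series: %d events on [0, %g]", length(x$times), x$T))
  if (length(x$times)) cat(sprintf(" (mean rate %.4g/time)", length(x$times) / x$T))
  if (!is.null(x$node_ids))
    cat(sprintf(", %d distinct nodes", length(unique(x$node_ids))))
  cat("\n")
  invisible(x)
}

as_event_series <- function(x, T = NULL) {
  if (inherits(x, "event_series")) return(x)
  if (is.numeric(x)) return(event_series(x, T = T))
  stop("expected an event_series or a numeric vector of times", call. = FALSE)
}

#' Write / read an event series as plain text
#'
#' The format is one event per line, `time` or `time node`, whitespace
#' delimited, with `#` comment headers carrying the observation span `T`
#' (and the node count when tagged).  Round-trips at full double precision.
#'
#' @param es an [event_series()].
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   [event_series()].
#' @export
write_events <- function(es, path) {
  es <- as_event_series(es)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# event series: T=%s", format(es$T, digits = 17)), con)
  if (!is.null(es$node_ids)) {
    writeLines("# columns: time node (node ids are 1-based)", con)
    writeLines(paste(format(es$times, digits = 17, trim = TRUE), es$node_ids), con)
  } else {
    writeLines("# columns: time", con)
    writeLines(format(es$times, digits = 17, trim = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  Tspan <- NULL
  m <- regmatches(hdr, regexpr("T=[0-9eE.+-]+", hdr))
  if (length(m)) Tspan <- as.numeric(sub("T=", "", m[[1]]))
  body <- grep("^\\s*(#|$)", lines, invert = TRUE)
  if (!length(body)) return(event_series(numeric(0), T = Tspan))
  fields <- strsplit(trimws(lines[body]), "\\s+")
  ncol <- lengths(fields)
  if (any(ncol != ncol[1]))
    stop(sprintf("malformed event file '%s': inconsistent columns at line %d",
                 path, body[which(ncol != ncol[1])[1]]), call. = FALSE)
  times <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  if (anyNA(times))
    stop(sprintf("malformed event file '%s': non-numeric time at line %d",
                 path, body[which(is.na(times))[1]]), call. = FALSE)
  ids <- if (ncol[1] >= 2L) as.integer(vapply(fields, `[[`, "", 2L)) else NULL
  event_series(times, T = Tspan, node_ids = ids)
}
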