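#' Per-frame scalar metric time series
#'
#' @param name metric name.
#' @param units unit string (e.g. "Angstrom", "count", "degrees").
#' @param times frame times in ns.
#' @param values one value per frame (NA allowed for missing).
#' @return a \code{metric_series} object.
#' @export
metric_series <- function(name, units, times, values) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  structure(list(name = name, units = units,
                 times = as.numeric(times), values = as.numeric(values)),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("MetricSeries '%s' [%s]: %d frames, range %.4g..%.4g\n",
              x$name, x$units, length(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
as.data.frame.metric_series <- function(x, ...) {
  data.frame(time_ns = x$times, value = x$values)
}

#' Write a metric series to CSV (columns time_ns, value)
#'
#' Values are written with full double precision so that a write/read
#' round trip reproduces them to better than 1e-9.
#'
#' @param series a \code{metric_series}.
#' @param path output CSV path.
#' @export
write_metric_csv <- function(series, path) {
  df <- data.frame(time_ns = format(series$times, digits = 17, trim = TRUE),
                   value = format(series$values, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metric series from CSV
#'
#' @param path CSV path written by \code{\link{write_metric_csv}}.
#' @param name,units metadata to attach (not stored in the CSV).
#' @export
read_metric_csv <- function(path, name = basename(path), units = "") {
  df <- utils::read.csv(path)
  metric_series(name, units, df$time_ns, df$value)
}
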