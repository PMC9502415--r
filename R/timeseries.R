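## Windowed per-frame scalar observables and distance histograms.

new_timeseries <- function(times, values, units = "") {
  stopifnot(length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("time series times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 units = units), class = "TimeSeries")
}

#' @export
print.TimeSeries <- function(x, ...) {
  cat(sprintf("TimeSeries: %d frames, mean %.4g %s\n", length(x$values),
              mean(x$values), x$units))
  invisible(x)
}

#' @export
as.data.frame.TimeSeries <- function(x, ...) {
  data.frame(time_ns = x$times, value = x$values)
}

#' @export
mean.TimeSeries <- function(x, ...) mean(x$values, ...)

#' Bin scalar values into a histogram
#'
#' Bins are half-open `[edge_i, edge_{i+1})`; the default grid (0.25 A bins
#' over 0-12 A) matches the distance-distribution reporting. The upper edge
#' is extended when values exceed it so that counts always sum to `n`.
#'
#' @param values numeric observations.
#' @param edges strictly increasing bin edges.
#' @return A `Histogram`: list with `edges`, `counts`, `n`.
#' @export
make_histogram <- function(values, edges = seq(0, 12, by = 0.25)) {
  stopifnot(length(values) > 0, all(diff(edges) > 0))
  if (any(values < edges[1])) {
    stop("values below the first histogram edge", call. = FALSE)
  }
  vmax <- max(values)
  w <- diff(edges)[length(edges) - 1]
  while (vmax >= edges[length(edges)]) {
    edges <- c(edges, edges[length(edges)] + w)
  }
  bin <- findInterval(values, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  structure(list(edges = edges, counts = counts, n = length(values)),
            class = "Histogram")
}

#' @export
print.Histogram <- function(x, ...) {
  cat("Histogram:", x$n, "values in", length(x$counts), "bins over [",
      x$edges[1], ",", x$edges[length(x$edges)], ") A\n")
  invisible(x)
}

## Write a TimeSeries as a two-column CSV.
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
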