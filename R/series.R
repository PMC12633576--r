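#' Uniformly sampled time series
#'
#' Lightweight carrier for a regularly sampled signal: sample values, the
#' sampling rate in Hz and the time of the first sample. All signal-level
#' operations in the package accept either a `uniform_series` or a bare
#' numeric vector plus an `fs` argument.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `uniform_series`.
#' @examples
#' s <- uniform_series(sin(2 * pi * 5 * seq(0, 1, by = 0.01)), fs = 100)
#' s$fs
#' @export
uniform_series <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("`values` must be finite and non-missing")
  }
  structure(list(values = values, fs = fs, t0 = t0),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series: %d samples @ %.4g Hz (%.3g s)>\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' @export
as.double.uniform_series <- function(x, ...) x$values

# Normalise (values, fs) from either a uniform_series or numeric + fs.
as_series <- function(x, fs = NULL) {
  if (inherits(x, "uniform_series")) return(x)
  if (is.null(fs)) stop("`fs` must be supplied when `x` is a bare vector")
  uniform_series(x, fs)
}

#' @describeIn uniform_series Convert to a two-column tibble (time, value).
#' @param x A `uniform_series`.
#' @param ... Unused.
#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.uniform_series <- function(x, ...) {
  tibble::tibble(
    time = x$t0 + seq_along(x$values[]) / x$fs - 1 / x$fs,
    value = x$values
  )
}
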