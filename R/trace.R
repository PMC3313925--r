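#' Kinetic trace container
#'
#' A time series of a normalized kinetic observable (deoxy fraction,
#' unbound fraction or bound fraction depending on the experiment mode)
#' together with the [conditions()] it was recorded or simulated under.
#'
#' @param times times in seconds, strictly increasing.
#' @param signal dimensionless signal, same length as `times`.
#' @param conditions a [conditions()] object (optional for purely
#'   mathematical traces).
#' @param sigma known additive noise standard deviation, if any.
#' @return Object of class `kinetic_trace`: a data.frame with columns
#'   `time`, `signal` and attributes `conditions`, `sigma`.
#' @export
kinetic_trace <- function(times, signal, conditions = NULL, sigma = NULL) {
  if (length(times) != length(signal))
    stop("times and signal lengths differ")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(signal)))
    stop("signal contains non-finite values")
  structure(data.frame(time = as.numeric(times), signal = as.numeric(signal)),
            conditions = conditions, sigma = sigma,
            class = c("kinetic_trace", "data.frame"))
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("<kinetic_trace> %d points, %.3g-%.3g s\n",
              nrow(x), x$time[1], x$time[nrow(x)]))
  if (!is.null(cond))
    cat(sprintf("  %s, T = %.2f K, [CO] = %.3g M\n",
                cond$mode, cond$temperature_K, cond$co_molar))
  if (!is.null(attr(x, "sigma")))
    cat(sprintf("  noise sigma = %.3g\n", attr(x, "sigma")))
  invisible(x)
}

#' Logarithmically spaced time grid
#'
#' @param from,to window limits (s), both `> 0`.
#' @param n number of points.
#' @return Numeric vector of `n` log-spaced times.
#' @export
log_time_grid <- function(from = 1e-8, to = 1e-2, n = 150) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  10^seq(log10(from), log10(to), length.out = n)
}
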