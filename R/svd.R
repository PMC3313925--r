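#' Singular value decomposition of a difference-spectra matrix
#'
#' Full SVD of the wavelength x delay matrix, with the lag-1
#' autocorrelation of every (unit-norm) left and right singular vector —
#' the standard statistic for separating smooth, physically meaningful
#' components from noise.  Signs are fixed so the largest-magnitude element
#' of each spectral vector is positive, making results reproducible.
#'
#' @param spectra a [spectra_set()] (or plain matrix).
#' @return Object of class `svd_result`: `u` (wavelength x rank), `d`
#'   (singular values, non-increasing), `v` (delay x rank),
#'   `autocorr_u`, `autocorr_v`, plus the input axes.
#' @export
decompose <- function(spectra) {
  M <- if (inherits(spectra, "spectra_set")) spectra$dA else as.matrix(spectra)
  if (any(!is.finite(M))) stop("spectra matrix contains non-finite entries")
  s <- svd(M)
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) { s$u[, j] <- -s$u[, j]; s$v[, j] <- -s$v[, j] }
  }
  lag1 <- function(x) sum(x[-length(x)] * x[-1])
  structure(list(u = s$u, d = s$d, v = s$v,
                 autocorr_u = apply(s$u, 2, lag1),
                 autocorr_v = apply(s$v, 2, lag1),
                 wavelengths = if (inherits(spectra, "spectra_set"))
                   spectra$wavelengths else NULL,
                 delays = if (inherits(spectra, "spectra_set"))
                   spectra$delays else NULL),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  k <- min(5, length(x$d))
  cat("<svd_result> leading singular values:\n")
  print(data.frame(S = x$d[1:k],
                   autocorr_U = x$autocorr_u[1:k],
                   autocorr_V = x$autocorr_v[1:k]), digits = 3)
  invisible(x)
}

#' Select significant SVD components by autocorrelation
#'
#' A component is significant when both its spectral and its temporal
#' vector have lag-1 autocorrelation above the threshold (default 0.8,
#' common practice for time-resolved spectra).
#'
#' @param result an `svd_result` from [decompose()].
#' @param autocorr_threshold significance threshold.
#' @return Integer vector of significant component indices.
#' @export
select_components <- function(result, autocorr_threshold = 0.8) {
  which(result$autocorr_u > autocorr_threshold &
          result$autocorr_v > autocorr_threshold)
}

#' Fit a temporal SVD component with a sum of stretched exponentials
#'
#' Convenience wrapper around [fit_multiexponential()] for the time course
#' of an SVD amplitude (typically the second component, which tracks the
#' r-to-t structural relaxation).  A free offset is always included since
#' SVD amplitudes carry an arbitrary baseline.
#'
#' @param result an `svd_result` with a `delays` axis.
#' @param component column index of `v` to fit.
#' @param n_components number of relaxations.
#' @param stretched fit stretching exponents (default `TRUE`).
#' @param ... passed to [fit_multiexponential()].
#' @return A `fit_result`.
#' @export
component_course_fit <- function(result, component = 2, n_components = 3,
                                 stretched = TRUE, ...) {
  if (is.null(result$delays))
    stop("svd_result carries no delay axis; decompose a spectra_set")
  tr <- kinetic_trace(result$delays, result$v[, component])
  fit_multiexponential(tr, n_components = n_components,
                       stretched = stretched, offset = TRUE, ...)
}

#' Principal angles between two column subspaces
#'
#' Used to verify that the significant SVD subspace spans a set of known
#' generating spectra.
#'
#' @param A,B matrices whose columns span the two subspaces.
#' @return Principal angles in degrees, ascending.
#' @export
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1)) * 180 / pi
}
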