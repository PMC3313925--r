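#' Simulate a flash-photolysis CO-rebinding trace
#'
#' Integrates the reaction scheme from the photolysed initial condition,
#' projects the deoxy-fraction observable, samples it on a logarithmic time
#' grid and adds i.i.d. Gaussian noise.  The defaults emulate nanosecond
#' laser photolysis monitored over 10 ns to 10 ms.
#'
#' @param rates a [rate_set()].
#' @param cond a [conditions()] with mode `"flash_photolysis"`.
#' @param n_points number of log-spaced samples.
#' @param t_min,t_max sampling window (s).
#' @param sigma additive Gaussian noise standard deviation (signal is of
#'   order 1); the default 2e-3 is typical of averaged single-wavelength
#'   transients.
#' @param seed RNG seed; mandatory so every generated trace is
#'   reproducible.
#' @return A [kinetic_trace()] with `sigma` recorded.
#' @export
make_flash_trace <- function(rates, cond, n_points = 150,
                             t_min = 1e-8, t_max = 1e-2,
                             sigma = 2e-3, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(cond$mode == "flash_photolysis")
  times <- log_time_grid(t_min, t_max, n_points)
  traj <- integrate_scheme(rates, cond, times)
  tr <- observable(traj, cond)
  add_trace_noise(tr, sigma, seed)
}

#' Simulate a stopped-flow trace (association or NO-displacement)
#'
#' Association traces follow CO binding to the unliganded protein after
#' mixing (mass-action CO depletion on by default); dissociation traces
#' follow the loss of bound CO when rebinding is suppressed by NO
#' scavenging.  Samples earlier than the instrument dead time are
#' discarded.
#'
#' @param rates a [rate_set()].
#' @param cond a [conditions()] with a stopped-flow mode.
#' @param dead_time instrument dead time (s), samples before it dropped.
#' @param duration total observation window (s).
#' @param n_points number of samples (log-spaced from the dead time).
#' @param sigma additive Gaussian noise sd (default 5e-3).
#' @param seed RNG seed, mandatory.
#' @return A [kinetic_trace()].
#' @export
make_stopped_flow_trace <- function(rates, cond, dead_time = 1e-3,
                                    duration = NULL, n_points = 150,
                                    sigma = 5e-3, seed) {
  if (missing(seed)) stop("a seed is required")
  if (dead_time < 0) stop("dead_time must be >= 0")
  stopifnot(cond$mode %in% c("stopped_flow_association",
                             "dissociation_NO_displacement"))
  if (is.null(duration))
    duration <- if (cond$mode == "stopped_flow_association") 10 else 200
  t0 <- max(dead_time, 1e-4)
  times <- log_time_grid(t0, duration, n_points)
  traj <- integrate_scheme(rates, cond, times)
  tr <- observable(traj, cond)
  add_trace_noise(tr, sigma, seed)
}

add_trace_noise <- function(trace, sigma, seed) {
  set.seed(seed)
  sig <- trace$signal + stats::rnorm(nrow(trace), sd = sigma)
  out <- kinetic_trace(trace$time, sig,
                       conditions = attr(trace, "conditions"),
                       sigma = sigma)
  attr(out, "meta") <- list(seed = as.character(seed))
  out
}

#' Time-resolved difference-spectra container
#'
#' @param wavelengths ascending wavelengths (nm).
#' @param delays strictly increasing delays (s).
#' @param dA difference-absorbance matrix, wavelength x delay.
#' @param sigma additive noise sd, if known.
#' @return Object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, delays, dA, sigma = NULL) {
  dA <- as.matrix(dA)
  if (nrow(dA) != length(wavelengths) || ncol(dA) != length(delays))
    stop("dA dimensions must be wavelength x delay")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be ascending")
  structure(list(wavelengths = as.numeric(wavelengths),
                 delays = as.numeric(delays),
                 dA = dA, sigma = sigma),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d wavelengths x %d delays (%.3g-%.3g s)\n",
              length(x$wavelengths), length(x$delays),
              x$delays[1], x$delays[length(x$delays)]))
  invisible(x)
}

#' Gaussian-band basis spectrum
#'
#' @param wavelengths evaluation grid (nm).
#' @param centers,widths,amplitudes band parameters (nm, nm, AU);
#'   `widths > 0`.
#' @return Numeric vector over `wavelengths`.
#' @export
band_spectrum <- function(wavelengths, centers, widths, amplitudes) {
  if (any(widths <= 0)) stop("band widths must be > 0")
  stopifnot(length(centers) == length(widths),
            length(centers) == length(amplitudes))
  out <- numeric(length(wavelengths))
  for (i in seq_along(centers))
    out <- out + amplitudes[i] * exp(-((wavelengths - centers[i])^2) /
                                       (2 * widths[i]^2))
  out
}

default_spectral_components <- function(wavelengths) {
  # deoxy-minus-CO difference: positive deoxy Soret near 436 nm, CO bleach
  # near 419 nm; second component a small shape change of the same bands
  list(
    list(spectrum = band_spectrum(wavelengths,
                                  centers = c(436, 419),
                                  widths = c(7, 6),
                                  amplitudes = c(1, -0.9))),
    list(spectrum = band_spectrum(wavelengths,
                                  centers = c(430, 442),
                                  widths = c(6, 6),
                                  amplitudes = c(0.05, -0.04)))
  )
}

#' Simulate a time-resolved difference-spectra matrix
#'
#' Builds `dA(lambda, t) = sum_i spectrum_i(lambda) * course_i(t)` plus
#' Gaussian noise.  With the default two components, the first time course
#' is the ligand-rebinding deoxy fraction and the second the normalized
#' occupancy of the t branch photoproduct (`U_t + P_t`), the marker of the
#' r-to-t structural relaxation.
#'
#' @param rates a [rate_set()].
#' @param cond a [conditions()] with mode `"flash_photolysis"`.
#' @param wavelengths evaluation grid (nm).
#' @param delays delay grid (s); default 70 log-spaced points, 10 ns-10 ms.
#' @param components list of `>= 1` components; each a list with element
#'   `spectrum` (vector over `wavelengths`) and optionally `course`
#'   (vector over `delays`).  Components without a `course` get the model
#'   courses described above (first: deoxy fraction; second: t-branch
#'   occupancy).
#' @param sigma additive Gaussian noise sd (absorbance units).
#' @param seed RNG seed, mandatory when `sigma > 0`.
#' @return A [spectra_set()] with attribute `truth` holding the noiseless
#'   spectra/courses actually used.
#' @export
make_spectra <- function(rates, cond,
                         wavelengths = seq(400, 460, by = 0.5),
                         delays = log_time_grid(1e-8, 1e-2, 70),
                         components = NULL,
                         sigma = 2e-4, seed = NULL) {
  if (sigma > 0 && is.null(seed)) stop("a seed is required when sigma > 0")
  if (is.null(components))
    components <- default_spectral_components(wavelengths)
  if (length(components) < 1) stop("need at least one component")
  need_course <- vapply(components, function(co) is.null(co$course), TRUE)
  if (any(need_course)) {
    traj <- integrate_scheme(rates, cond, delays)
    deoxy <- observable(traj, cond)$signal
    tmark <- (traj$Ut + traj$Pt) / (cond$phi * cond$protein_molar)
    model_courses <- list(deoxy, tmark / max(tmark))
    for (i in seq_along(components)) {
      if (need_course[i]) {
        if (i > length(model_courses))
          stop("no default course for component ", i, "; supply one")
        components[[i]]$course <- model_courses[[i]]
      }
    }
  }
  dA <- matrix(0, length(wavelengths), length(delays))
  for (co in components) {
    if (length(co$spectrum) != length(wavelengths) ||
        length(co$course) != length(delays))
      stop("component axes do not match the wavelength/delay grids")
    dA <- dA + outer(co$spectrum, co$course)
  }
  truth <- components
  if (sigma > 0) {
    set.seed(seed)
    dA <- dA + matrix(stats::rnorm(length(dA), sd = sigma),
                      nrow(dA), ncol(dA))
  }
  out <- spectra_set(wavelengths, delays, dA, sigma = sigma)
  attr(out, "truth") <- truth
  out
}

#' Evaluate a sum of (stretched) exponential relaxations
#'
#' `y(t) = y0 + sum_i A_i exp(-(t/tau_i)^beta_i)`.
#'
#' @param times times (s).
#' @param amplitudes,taus,betas component parameters.
#' @param y0 constant offset.
#' @return Numeric vector over `times`.
#' @export
multiexp_curve <- function(times, amplitudes, taus, betas = NULL, y0 = 0) {
  if (is.null(betas)) betas <- rep(1, length(taus))
  stopifnot(length(amplitudes) == length(taus),
            length(betas) == length(taus))
  y <- rep(y0, length(times))
  for (i in seq_along(taus))
    y <- y + amplitudes[i] * exp(-(times / taus[i])^betas[i])
  y
}
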