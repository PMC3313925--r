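# Physical constants (CODATA); R in kcal/mol/K, kB/h in K^-1 s^-1
.R_KCAL <- 1.987204258640832e-3
.KB_OVER_H <- 1.380649e-23 / 6.62607015e-34

#' Activation free energy from a rate constant (Eyring equation)
#'
#' `dG = R T ln(kB T / (h k))` with transmission coefficient 1.
#' Second-order rate constants are interpreted on a 1 M standard state, so
#' their numeric value in M^-1 s^-1 enters the formula directly.
#'
#' @param k rate constant (s^-1, or M^-1 s^-1 for second-order steps),
#'   `> 0`.
#' @param temperature_K absolute temperature, `> 0`.
#' @return Activation free energy in kcal/mol.
#' @export
#' @examples
#' dg_from_rate(5.5e7, 298.15)  # ~6.9 kcal/mol
dg_from_rate <- function(k, temperature_K = 298.15) {
  if (any(k <= 0)) stop("rate constants must be > 0")
  if (any(temperature_K <= 0)) stop("temperature must be > 0")
  .R_KCAL * temperature_K * log(.KB_OVER_H * temperature_K / k)
}

#' Activation parameters for a single rate constant
#'
#' @param dH activation enthalpy (kcal/mol).
#' @param dS activation entropy (kcal/mol/K).
#' @param dH_se,dS_se optional standard errors.
#' @param cov_HS optional covariance of the two estimates (from a fit).
#' @return Object of class `activation_params`.
#' @export
activation_params <- function(dH, dS, dH_se = NA_real_, dS_se = NA_real_,
                              cov_HS = 0) {
  structure(list(dH = dH, dS = dS, dH_se = dH_se, dS_se = dS_se,
                 cov_HS = cov_HS),
            class = "activation_params")
}

#' @export
print.activation_params <- function(x, ...) {
  cat(sprintf("<activation_params> dH = %.4g kcal/mol (se %.2g), dS = %.4g kcal/mol/K (se %.2g)\n",
              x$dH, x$dH_se, x$dS, x$dS_se))
  cat(sprintf("  dG(298.15 K) = %.4g kcal/mol\n", dg_at(x, 298.15)))
  invisible(x)
}

#' Activation free energy at a temperature, with propagated error
#'
#' @param params an [activation_params()].
#' @param temperature_K temperature (K).
#' @return `dg_at()` the value; `dg_se_at()` its standard error.
#' @export
dg_at <- function(params, temperature_K = 298.15) {
  params$dH - temperature_K * params$dS
}

#' @rdname dg_at
#' @export
dg_se_at <- function(params, temperature_K = 298.15) {
  sqrt(params$dH_se^2 + temperature_K^2 * params$dS_se^2 -
         2 * temperature_K * params$cov_HS)
}

#' Rate constant at a temperature from activation parameters
#'
#' Inverse of the Eyring relation:
#' `k(T) = (kB T / h) exp(-dH/(R T) + dS/R)`.
#'
#' @param params an [activation_params()].
#' @param temperature_K temperature (K).
#' @return Rate constant (same order/standard state as the data the
#'   parameters were derived from).
#' @export
rate_at_temperature <- function(params, temperature_K) {
  .KB_OVER_H * temperature_K *
    exp(-params$dH / (.R_KCAL * temperature_K) + params$dS / .R_KCAL)
}

#' Linear Eyring fit of a temperature series of rate constants
#'
#' Ordinary least squares of `ln(k h / (kB T))` against `1/T`; the slope is
#' `-dH/R` and the intercept `dS/R`.  Standard errors and the
#' slope-intercept covariance are propagated so that `dG(T)` errors are
#' available via [dg_se_at()].
#'
#' @param temperatures_K `>= 3` temperatures spanning at least 10 K.
#' @param rates corresponding positive rate constants.
#' @return An [activation_params()] with standard errors, plus fields
#'   `fit` (the underlying `lm`) and `residual_se`.
#' @export
fit_eyring <- function(temperatures_K, rates) {
  if (length(temperatures_K) != length(rates))
    stop("temperatures and rates lengths differ")
  if (length(rates) < 3) stop("need at least 3 temperatures")
  if (diff(range(temperatures_K)) < 10)
    stop("temperature span must be at least 10 K")
  if (any(rates <= 0)) stop("rate constants must be > 0")
  y <- log(rates / (.KB_OVER_H * temperatures_K))
  x <- 1 / temperatures_K
  fit <- stats::lm(y ~ x)
  # covariance assembled directly from the QR factors; summary.lm warns on
  # the (legitimate) noiseless case
  s2 <- sum(stats::residuals(fit)^2) / max(length(y) - 2, 1)
  V <- chol2inv(qr.R(fit$qr)) * s2
  dimnames(V) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))
  co <- stats::coef(fit)
  p <- activation_params(
    dH = -.R_KCAL * co[["x"]],
    dS = .R_KCAL * co[["(Intercept)"]],
    dH_se = .R_KCAL * sqrt(V["x", "x"]),
    dS_se = .R_KCAL * sqrt(V["(Intercept)", "(Intercept)"]),
    # cov(dH, dS) = -R^2 cov(slope, intercept)
    cov_HS = -.R_KCAL^2 * V["x", "(Intercept)"])
  p$fit <- fit
  p$residual_se <- sqrt(sum(stats::residuals(fit)^2) /
                          max(length(rates) - 2, 1))
  p
}

#' Eyring analysis of a full rate set across temperatures
#'
#' Fits every rate constant's temperature series and tabulates dH, dS and
#' dG at a reference temperature.
#'
#' @param temperatures_K vector of temperatures.
#' @param rate_sets list of [rate_set()]s, one per temperature.
#' @param t_ref reference temperature for dG reporting (K).
#' @return data.frame with one row per rate constant: `rate`, `dH`, `dS`,
#'   `dG_ref`, and standard errors.
#' @export
eyring_table <- function(temperatures_K, rate_sets, t_ref = 298.15) {
  stopifnot(length(temperatures_K) == length(rate_sets))
  rows <- lapply(rate_names(), function(nm) {
    ks <- vapply(rate_sets, function(r) unclass(r)[[nm]], 0)
    p <- fit_eyring(temperatures_K, ks)
    data.frame(rate = nm, dH = p$dH, dH_se = p$dH_se,
               dS = p$dS, dS_se = p$dS_se,
               dG_ref = dg_at(p, t_ref), dG_se = dg_se_at(p, t_ref))
  })
  do.call(rbind, rows)
}
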