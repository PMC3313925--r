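#' Multi-exponential and stretched-exponential trace fitting
#'
#' Fits `y(t) = y0 + sum_i A_i exp(-(t/tau_i)^beta_i)` by trust-region
#' Levenberg-Marquardt least squares (`minpack.lm`).  Lifetimes are
#' optimized in log10 space; stretching exponents, when enabled, are
#' bounded to `(0.2, 1]` to avoid the degenerate flat-plateau limit.
#' Components are reported sorted by ascending lifetime, with amplitudes
#' also expressed as fractions of the total absolute amplitude.
#'
#' @param trace a [kinetic_trace()] (or data.frame with `time`, `signal`).
#' @param n_components number of exponential components, `>= 1`.
#' @param stretched if `TRUE`, each component gets a free stretching
#'   exponent `beta_i`; otherwise `beta_i = 1`.
#' @param offset if `TRUE` (default) a free constant `y0` is included.
#' @param init optional list with starting values: `amplitudes`, `taus`,
#'   optionally `betas` and `y0`.  If omitted, a deterministic multi-start
#'   over lifetime placements is used.
#' @param n_starts number of starts when `init` is not given.
#' @param max_iter maximum optimizer iterations per start.
#' @return A `fit_result` list: `components` (data.frame with `amplitude`,
#'   `tau`, `beta`, `fraction`), `y0`, `rss`, `chisq` (RSS/sigma^2 when the
#'   trace carries a noise sd), `converged`, `fitted`, `residuals`,
#'   `covariance`.
#' @export
fit_multiexponential <- function(trace, n_components = 2, stretched = FALSE,
                                 offset = TRUE, init = NULL, n_starts = 8,
                                 max_iter = 200) {
  t <- trace$time; y <- trace$signal
  if (n_components < 1) stop("n_components must be >= 1")
  if (length(t) < 5 * n_components)
    stop("need at least 5 points per exponential component")
  lt_lo <- log10(min(t)) - 2; lt_hi <- log10(max(t)) + 2

  pack <- function(A, lt, beta, y0) c(A, lt, if (stretched) beta, if (offset) y0)
  unpack <- function(p) {
    A <- p[seq_len(n_components)]
    lt <- p[n_components + seq_len(n_components)]
    i <- 2 * n_components
    beta <- if (stretched) { b <- p[i + seq_len(n_components)]; i <- i + n_components; b }
            else rep(1, n_components)
    y0 <- if (offset) p[i + 1] else 0
    list(A = A, tau = 10^lt, beta = beta, y0 = y0)
  }
  residfun <- function(p) {
    q <- unpack(p)
    multiexp_curve(t, q$A, q$tau, q$beta, q$y0) - y
  }
  lower <- pack(rep(-Inf, n_components), rep(lt_lo, n_components),
                rep(0.2, n_components), -Inf)
  upper <- pack(rep(Inf, n_components), rep(lt_hi, n_components),
                rep(1, n_components), Inf)

  starts <- list()
  if (!is.null(init)) {
    b0 <- init$betas %||% rep(if (stretched) 0.8 else 1, n_components)
    starts[[1]] <- pack(init$amplitudes, log10(init$taus), b0, init$y0 %||% 0)
  } else {
    span <- log10(max(t)) - log10(min(t))
    amp0 <- (max(y) - min(y)) / n_components
    for (s in seq_len(n_starts)) {
      # deterministic lattice of lifetime placements across the window
      off <- (s - 1) / n_starts - 0.5
      lt0 <- log10(min(t)) + span * ((seq_len(n_components) - 0.5) / n_components + off / n_components)
      lt0 <- pmin(pmax(lt0, lt_lo), lt_hi)
      starts[[s]] <- pack(rep(amp0, n_components), lt0,
                          rep(0.8, n_components), min(y))
    }
  }

  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = residfun,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = 1e-12, ptol = 1e-12)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all multiexponential fit starts failed")

  q <- unpack(best$par)
  ord <- order(q$tau)
  comps <- data.frame(amplitude = q$A[ord], tau = q$tau[ord],
                      beta = q$beta[ord])
  # exchangeable components that converged onto the same lifetime describe
  # one relaxation; consolidate their amplitudes deterministically
  if (n_components > 1) {
    for (i in seq_len(nrow(comps) - 1)) {
      same <- abs(log(comps$tau[i + 1] / comps$tau[i])) < 1e-3 &&
        abs(comps$beta[i + 1] - comps$beta[i]) < 1e-3
      if (same) {
        comps$amplitude[i + 1] <- comps$amplitude[i + 1] + comps$amplitude[i]
        comps$amplitude[i] <- 0
      }
    }
  }
  comps$fraction <- abs(comps$amplitude) / sum(abs(comps$amplitude))
  rss <- best$deviance
  sigma <- attr(trace, "sigma")
  covar <- tryCatch({
    dof <- max(length(t) - length(best$par), 1)
    solve(best$hessian) * rss / dof
  }, error = function(e) NULL)
  structure(list(components = comps, y0 = q$y0, rss = rss,
                 chisq = if (!is.null(sigma)) rss / sigma^2 else NA_real_,
                 converged = best$info %in% 1:4,
                 info = best$info,
                 fitted = y + best$fvec, residuals = best$fvec,
                 n_points = length(t),
                 covariance = covar),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (isTRUE(x$converged)) "converged" else
      "NOT converged", "\n")
  if (!is.null(x$components)) print(x$components, digits = 4)
  if (!is.null(x$rates)) print(x$rates)
  cat(sprintf("  rss = %.4g", x$rss))
  if (!is.na(x$chisq %||% NA)) cat(sprintf(", chisq = %.4g", x$chisq))
  cat(sprintf(", y0 = %.4g\n", x$y0 %||% NA))
  invisible(x)
}

#' Second-order rate constant from apparent rates vs CO concentration
#'
#' Ordinary least-squares regression of pseudo-first-order apparent rates
#' on ligand concentration; the slope is the bimolecular association rate
#' constant.
#'
#' @param co_molar CO concentrations (mol/L), `>= 3` values.
#' @param k_obs apparent rates (s^-1).
#' @return List with `slope` (M^-1 s^-1), `slope_se`, `intercept`,
#'   `intercept_se` and the underlying `lm` fit.
#' @export
kobs_vs_concentration <- function(co_molar, k_obs) {
  if (length(co_molar) < 3) stop("need at least 3 concentrations")
  fit <- stats::lm(k_obs ~ co_molar)
  s2 <- sum(stats::residuals(fit)^2) / max(length(k_obs) - 2, 1)
  V <- chol2inv(qr.R(fit$qr)) * s2
  co <- stats::coef(fit)
  list(slope = co[["co_molar"]],
       slope_se = sqrt(V[2, 2]),
       intercept = co[["(Intercept)"]],
       intercept_se = sqrt(V[1, 1]),
       fit = fit)
}

#' Specification of a global multi-dataset scheme fit
#'
#' @param datasets list of [kinetic_trace()]s, each carrying its
#'   [conditions()]; `>= 1` (two or more differing conditions are what make
#'   the microscopic rates identifiable).
#' @param rates starting [rate_set()].
#' @param free names of the rate constants to optimize (in log space); the
#'   remainder stay fixed at their input values, bit-identical.
#' @param weight_sigma if `TRUE`, residuals are divided by each trace's
#'   noise sd when available.
#' @param multi_start number of optimizer starts; starts beyond the first
#'   perturb the free rates log-uniformly within `+/- start_spread`
#'   decades.
#' @param start_spread spread of the multi-start perturbation (decades).
#' @param seed RNG seed for the multi-start draws.
#' @param rtol integrator relative tolerance used inside the objective.
#' @param max_iter maximum optimizer iterations per start.
#' @return A `fit_spec` list, input to [global_fit()].
#' @export
fit_spec <- function(datasets, rates,
                     free = c("kin_r", "kin_t", "kg_r", "kg_t",
                              "k3", "km3", "kout"),
                     weight_sigma = TRUE, multi_start = 1,
                     start_spread = 0.5, seed = 1, rtol = 1e-8,
                     max_iter = 100, stop_deviance = NULL) {
  if (!length(datasets)) stop("need at least one dataset")
  for (d in datasets)
    if (is.null(attr(d, "conditions")))
      stop("every dataset must carry a conditions attribute")
  bad <- setdiff(free, rate_names())
  if (length(bad)) stop("unknown rate names in free: ", paste(bad, collapse = ", "))
  structure(list(datasets = datasets, rates = rates, free = free,
                 weight_sigma = weight_sigma, multi_start = multi_start,
                 start_spread = start_spread, seed = seed, rtol = rtol,
                 max_iter = max_iter, stop_deviance = stop_deviance),
            class = "fit_spec")
}

#' Global least-squares fit of the reaction scheme to multiple traces
#'
#' Minimizes the summed squared residuals between the simulated observable
#' and every dataset simultaneously, on each dataset's own (typically
#' log-spaced) time grid.  Free rate constants are optimized in log10
#' space, so they stay strictly positive by construction.  A parameter
#' vector for which the integrator fails scores an effectively infinite
#' residual and the failure is recorded.
#'
#' @param spec a [fit_spec()].
#' @return A `fit_result` with fields `rates` (fitted [rate_set()]),
#'   `se_log10` / `rel_se` (standard errors of the free parameters on the
#'   log10 and linear scale), `per_dataset_rss`, `rss`, `chisq`,
#'   `converged`, `n_failures` (integrator failures seen), `covariance`
#'   (log10 scale) and `starts` (per-start summary).
#' @export
global_fit <- function(spec) {
  rates0 <- unclass(spec$rates)
  free <- spec$free
  p0 <- log10(rates0[free])
  n_fail <- 0L

  sigmas <- vapply(spec$datasets, function(d) {
    s <- attr(d, "sigma")
    if (spec$weight_sigma && !is.null(s) && s > 0) s else 1
  }, 0)

  residfun <- function(p) {
    k <- rates0
    k[free] <- 10^p
    rs <- structure(k, class = "rate_set")
    res <- lapply(seq_along(spec$datasets), function(i) {
      d <- spec$datasets[[i]]
      cond <- attr(d, "conditions")
      sim <- try(observable(
        integrate_scheme(rs, cond, d$time, rtol = spec$rtol,
                         atol = 1e-10 * cond$protein_molar), cond),
        silent = TRUE)
      if (inherits(sim, "try-error")) {
        n_fail <<- n_fail + 1L
        return(rep(1e6, nrow(d)))
      }
      (sim$signal - d$signal) / sigmas[i]
    })
    unlist(res)
  }

  starts <- list(p0)
  if (spec$multi_start > 1) {
    set.seed(spec$seed)
    for (s in seq_len(spec$multi_start - 1))
      starts[[s + 1]] <- p0 + stats::runif(length(p0), -spec$start_spread,
                                           spec$start_spread)
  }

  best <- NULL; log <- NULL
  for (i in seq_along(starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[[i]], fn = residfun,
      control = minpack.lm::nls.lm.control(maxiter = spec$max_iter,
                                           ftol = 1e-10, ptol = 1e-10)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    log <- rbind(log, data.frame(start = i, deviance = fit$deviance,
                                 info = fit$info))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    # additional starts exist to escape local minima; once a start reaches
    # the requested deviance there is nothing left to escape from
    if (!is.null(spec$stop_deviance) && best$deviance <= spec$stop_deviance)
      break
  }
  if (is.null(best)) stop("all global fit starts failed")

  k <- rates0
  k[free] <- 10^best$par
  fitted_rates <- structure(k, class = "rate_set")

  n_tot <- sum(vapply(spec$datasets, nrow, 0L))
  dof <- max(n_tot - length(free), 1)
  covar <- tryCatch(solve(best$hessian) * best$deviance / dof,
                    error = function(e) NULL)
  se_log10 <- if (!is.null(covar))
    stats::setNames(sqrt(pmax(diag(covar), 0)), free) else NULL
  rel_se <- if (!is.null(se_log10)) abs(log(10)) * se_log10 else NULL

  # per-dataset residual norms at the optimum
  idx <- cumsum(vapply(spec$datasets, nrow, 0L))
  lo <- c(1, utils::head(idx, -1) + 1)
  per_rss <- vapply(seq_along(idx), function(i)
    sum(best$fvec[lo[i]:idx[i]]^2), 0)

  structure(list(rates = fitted_rates, free = free,
                 se_log10 = se_log10, rel_se = rel_se,
                 per_dataset_rss = per_rss,
                 rss = best$deviance, chisq = best$deviance,
                 converged = best$info %in% 1:4, info = best$info,
                 n_failures = n_fail, covariance = covar,
                 starts = log, y0 = 0),
            class = "fit_result")
}
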