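species_names <- function() c("Br", "Bt", "Pr", "Pt", "Sr", "St", "Ur", "Ut", "C")

#' Mass-action right-hand side of the two-conformation reaction scheme
#'
#' The network couples, for each conformation (r fast-rebinding, t
#' slow-rebinding), a CO-bound state `B`, a primary docking site `P`
#' (photoproduct with CO still in the distal pocket), a secondary docking
#' site `S` (transient internal cavity) and an unliganded state `U` with CO
#' in the solvent pool `C`:
#'
#' \preformatted{
#'   B_r <-> B_t   (k1 / km1)         P_r  -> B_r  (kg_r)
#'   P_r <-> P_t   (k2 / km2)         P_t  -> B_t  (kg_t)
#'   U_r <-> U_t   (k3 / km3)         B_r  -> P_r  (kdiss_r)
#'   P_r <-> S_r   (kmig_r / kret_r)  B_t  -> P_t  (kdiss_t)
#'   P_t <-> S_t   (kmig_t / kret_t)  P_rt -> U_rt + CO  (kout, shared)
#'   U_r + CO -> P_r  (kin_r C)       U_t + CO -> P_t  (kin_t C)
#' }
#'
#' Secondary docking sites neither exchange conformation nor rebind
#' directly; they only buffer the primary site.
#'
#' @param state named numeric vector of the nine species `Br, Bt, Pr, Pt,
#'   Sr, St, Ur, Ut, C` (mol/L, all `>= 0`).
#' @param rates a [rate_set()].
#' @param pseudo_first_order if `TRUE`, the free CO pool `C` is treated as
#'   constant (`dC/dt = 0`); protein mass action is unaffected.
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
ode_rhs <- function(state, rates, pseudo_first_order = TRUE) {
  if (any(!is.finite(state)) || any(state < 0))
    stop("state concentrations must be finite and non-negative")
  s <- as.numeric(state)
  k <- unclass(rates)
  Br <- s[1]; Bt <- s[2]; Pr <- s[3]; Pt <- s[4]
  Sr <- s[5]; St <- s[6]; Ur <- s[7]; Ut <- s[8]; C <- s[9]

  in_r <- k[["kin_r"]] * C * Ur
  in_t <- k[["kin_t"]] * C * Ut
  d <- c(
    Br = k[["kg_r"]] * Pr - k[["kdiss_r"]] * Br - k[["k1"]] * Br + k[["km1"]] * Bt,
    Bt = k[["kg_t"]] * Pt - k[["kdiss_t"]] * Bt + k[["k1"]] * Br - k[["km1"]] * Bt,
    Pr = k[["kdiss_r"]] * Br - (k[["kg_r"]] + k[["kout"]] + k[["kmig_r"]] + k[["k2"]]) * Pr +
         k[["km2"]] * Pt + k[["kret_r"]] * Sr + in_r,
    Pt = k[["kdiss_t"]] * Bt - (k[["kg_t"]] + k[["kout"]] + k[["kmig_t"]] + k[["km2"]]) * Pt +
         k[["k2"]] * Pr + k[["kret_t"]] * St + in_t,
    Sr = k[["kmig_r"]] * Pr - k[["kret_r"]] * Sr,
    St = k[["kmig_t"]] * Pt - k[["kret_t"]] * St,
    Ur = k[["kout"]] * Pr - in_r - k[["k3"]] * Ur + k[["km3"]] * Ut,
    Ut = k[["kout"]] * Pt - in_t + k[["k3"]] * Ur - k[["km3"]] * Ut,
    C  = if (pseudo_first_order) 0 else
         k[["kout"]] * (Pr + Pt) - in_r - in_t
  )
  d
}

#' Linear rate matrix of the protein subsystem at fixed CO
#'
#' Under the pseudo-first-order approximation the eight protein species
#' evolve linearly, `dx/dt = A x`.  Exposed mainly for analytic work
#' (eigen-solutions, steady states); [integrate_scheme()] is the general
#' route.
#'
#' @inheritParams ode_rhs
#' @param co_molar fixed free CO concentration (mol/L).
#' @return 8x8 matrix with rows/columns `Br, Bt, Pr, Pt, Sr, St, Ur, Ut`.
#' @export
rate_matrix <- function(rates, co_molar) {
  k <- unclass(rates)
  nm <- species_names()[1:8]
  A <- matrix(0, 8, 8, dimnames = list(nm, nm))
  A["Br", "Br"] <- -(k[["kdiss_r"]] + k[["k1"]]);  A["Br", "Bt"] <- k[["km1"]]
  A["Br", "Pr"] <- k[["kg_r"]]
  A["Bt", "Bt"] <- -(k[["kdiss_t"]] + k[["km1"]]); A["Bt", "Br"] <- k[["k1"]]
  A["Bt", "Pt"] <- k[["kg_t"]]
  A["Pr", "Br"] <- k[["kdiss_r"]]
  A["Pr", "Pr"] <- -(k[["kg_r"]] + k[["kout"]] + k[["kmig_r"]] + k[["k2"]])
  A["Pr", "Pt"] <- k[["km2"]]; A["Pr", "Sr"] <- k[["kret_r"]]
  A["Pr", "Ur"] <- k[["kin_r"]] * co_molar
  A["Pt", "Bt"] <- k[["kdiss_t"]]
  A["Pt", "Pt"] <- -(k[["kg_t"]] + k[["kout"]] + k[["kmig_t"]] + k[["km2"]])
  A["Pt", "Pr"] <- k[["k2"]]; A["Pt", "St"] <- k[["kret_t"]]
  A["Pt", "Ut"] <- k[["kin_t"]] * co_molar
  A["Sr", "Pr"] <- k[["kmig_r"]]; A["Sr", "Sr"] <- -k[["kret_r"]]
  A["St", "Pt"] <- k[["kmig_t"]]; A["St", "St"] <- -k[["kret_t"]]
  A["Ur", "Pr"] <- k[["kout"]]
  A["Ur", "Ur"] <- -(k[["kin_r"]] * co_molar + k[["k3"]])
  A["Ur", "Ut"] <- k[["km3"]]
  A["Ut", "Pt"] <- k[["kout"]]
  A["Ut", "Ut"] <- -(k[["kin_t"]] * co_molar + k[["km3"]])
  A["Ut", "Ur"] <- k[["k3"]]
  A
}

#' Initial state for each experiment mode
#'
#' * `flash_photolysis`: the CO-bound ensemble sits at the liganded
#'   conformational equilibrium, `f(B_r) = km1/(k1+km1)`; a fraction `phi`
#'   is promoted, conformational identity preserved, to the primary docking
#'   site.  With the published rates the photoproduct splits roughly 77/23
#'   between the r and t branch.
#' * `stopped_flow_association`: all protein unliganded at the deligated
#'   equilibrium `f(U_t) = k3/(k3+km3)`; CO at the post-mix concentration.
#' * `dissociation_NO_displacement`: bound ensemble at the liganded
#'   equilibrium; NO scavenging is represented by disabling re-entry
#'   (`kin_r = kin_t = 0`, see [dissociation_rates()]), so every CO that
#'   reaches the solvent is lost.
#'
#' @param cond a [conditions()] object.
#' @param rates a [rate_set()].
#' @return Named state vector (mol/L) suitable for [integrate_scheme()].
#' @export
initial_state <- function(cond, rates) {
  k <- unclass(rates)
  P <- cond$protein_molar
  s <- stats::setNames(numeric(9), species_names())
  if (cond$mode == "flash_photolysis") {
    fBr <- k[["km1"]] / (k[["k1"]] + k[["km1"]])
    fBt <- k[["k1"]] / (k[["k1"]] + k[["km1"]])
    phi <- cond$phi
    s["Br"] <- (1 - phi) * fBr * P
    s["Bt"] <- (1 - phi) * fBt * P
    s["Pr"] <- phi * fBr * P
    s["Pt"] <- phi * fBt * P
    s["C"] <- cond$co_molar
  } else if (cond$mode == "stopped_flow_association") {
    fUt <- k[["k3"]] / (k[["k3"]] + k[["km3"]])
    s["Ur"] <- (1 - fUt) * P
    s["Ut"] <- fUt * P
    s["C"] <- cond$co_molar
  } else { # dissociation_NO_displacement
    s["Br"] <- k[["km1"]] / (k[["k1"]] + k[["km1"]]) * P
    s["Bt"] <- k[["k1"]] / (k[["k1"]] + k[["km1"]]) * P
    s["C"] <- 0
  }
  s
}

#' Rate set with rebinding channels removed (NO-displacement convention)
#'
#' @param rates a [rate_set()].
#' @return The same rates with `kin_r = kin_t = 0`.
#' @export
dissociation_rates <- function(rates) {
  k <- unclass(rates)
  k[["kin_r"]] <- 0
  k[["kin_t"]] <- 0
  structure(k, class = "rate_set")
}

#' Integrate the reaction scheme on a time grid
#'
#' Stiff numerical integration (`deSolve`, lsoda with an analytic
#' Jacobian).  Default tolerances are `rtol = 1e-10` and
#' `atol = 1e-13 * protein_molar`, tight enough that total protein is
#' conserved to better than 1e-9 relative at every output time.
#'
#' @param rates a [rate_set()]; for dissociation mode the rebinding
#'   channels are switched off internally.
#' @param cond a [conditions()] object.
#' @param times strictly increasing times (s).  A leading `t = 0` is added
#'   internally if absent.
#' @param rtol,atol integrator tolerances.
#' @return A data.frame with columns `time` and the nine species
#'   concentrations (mol/L), one row per requested time.
#' @export
integrate_scheme <- function(rates, cond, times, rtol = 1e-10, atol = NULL) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (cond$mode == "dissociation_NO_displacement")
    rates <- dissociation_rates(rates)
  y0 <- initial_state(cond, rates)
  if (is.null(atol)) atol <- 1e-13 * cond$protein_molar
  pfo <- isTRUE(cond$pseudo_first_order)
  k <- unclass(rates)
  A <- rate_matrix(rates, cond$co_molar)

  deriv <- function(t, y, parms) {
    in_r <- k[["kin_r"]] * y[9] * y[7]
    in_t <- k[["kin_t"]] * y[9] * y[8]
    d1 <- k[["kg_r"]] * y[3] - (k[["kdiss_r"]] + k[["k1"]]) * y[1] + k[["km1"]] * y[2]
    d2 <- k[["kg_t"]] * y[4] - (k[["kdiss_t"]] + k[["km1"]]) * y[2] + k[["k1"]] * y[1]
    d3 <- k[["kdiss_r"]] * y[1] - (k[["kg_r"]] + k[["kout"]] + k[["kmig_r"]] + k[["k2"]]) * y[3] +
      k[["km2"]] * y[4] + k[["kret_r"]] * y[5] + in_r
    d4 <- k[["kdiss_t"]] * y[2] - (k[["kg_t"]] + k[["kout"]] + k[["kmig_t"]] + k[["km2"]]) * y[4] +
      k[["k2"]] * y[3] + k[["kret_t"]] * y[6] + in_t
    d5 <- k[["kmig_r"]] * y[3] - k[["kret_r"]] * y[5]
    d6 <- k[["kmig_t"]] * y[4] - k[["kret_t"]] * y[6]
    d7 <- k[["kout"]] * y[3] - in_r - k[["k3"]] * y[7] + k[["km3"]] * y[8]
    d8 <- k[["kout"]] * y[4] - in_t + k[["k3"]] * y[7] - k[["km3"]] * y[8]
    d9 <- if (pfo) 0 else k[["kout"]] * (y[3] + y[4]) - in_r - in_t
    list(c(d1, d2, d3, d4, d5, d6, d7, d8, d9))
  }

  jac <- function(t, y, parms) {
    J <- matrix(0, 9, 9)
    J[1:8, 1:8] <- A
    if (pfo) {
      # P-rows already carry kin*C0 in A; U-rows likewise
      return(J)
    }
    # mass action: replace the CO-dependent entries with state-dependent ones
    J[3, 7] <- k[["kin_r"]] * y[9]; J[3, 9] <- k[["kin_r"]] * y[7]
    J[4, 8] <- k[["kin_t"]] * y[9]; J[4, 9] <- k[["kin_t"]] * y[8]
    J[7, 7] <- -(k[["kin_r"]] * y[9] + k[["k3"]]); J[7, 9] <- -k[["kin_r"]] * y[7]
    J[8, 8] <- -(k[["kin_t"]] * y[9] + k[["km3"]]); J[8, 9] <- -k[["kin_t"]] * y[8]
    J[9, 3] <- k[["kout"]]; J[9, 4] <- k[["kout"]]
    J[9, 7] <- -k[["kin_r"]] * y[9]; J[9, 8] <- -k[["kin_t"]] * y[9]
    J[9, 9] <- -(k[["kin_r"]] * y[7] + k[["kin_t"]] * y[8])
    J
  }

  tt <- if (times[1] > 0) c(0, times) else times
  out <- tryCatch(
    deSolve::lsoda(y = y0, times = tt, func = deriv, parms = NULL,
                   jacfunc = jac, jactype = "fullusr",
                   rtol = rtol, atol = atol, maxsteps = 50000),
    warning = function(w) {
      stop(sprintf("integration failed (%s) [mode=%s, T=%.1fK, CO=%.3gM]",
                   conditionMessage(w), cond$mode, cond$temperature_K,
                   cond$co_molar), call. = FALSE)
    })
  out <- as.data.frame(out)
  names(out) <- c("time", species_names())
  res <- out[match(times, out$time), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Project species trajectories onto the measured observable
#'
#' * flash photolysis: fraction of deoxy haems,
#'   `N(t) = (P+S+U)/(photolysed amount)`, so `N` starts near 1;
#' * stopped-flow association: unbound protein fraction (mirrors the
#'   absorbance decay at 418 nm);
#' * NO-displacement dissociation: bound fraction (mirrors 421 nm).
#'
#' @param traj data.frame from [integrate_scheme()].
#' @param cond the [conditions()] used to produce it.
#' @return A [kinetic_trace()].
#' @export
observable <- function(traj, cond) {
  unbound <- traj$Pr + traj$Pt + traj$Sr + traj$St + traj$Ur + traj$Ut
  # an unphotolysed control has no photoproduct to normalize by; fall back
  # to the total protein so the observable is simply the deoxy fraction
  flash_denom <- if (cond$phi > 0) cond$phi * cond$protein_molar
                 else cond$protein_molar
  sig <- switch(cond$mode,
    flash_photolysis = unbound / flash_denom,
    stopped_flow_association = unbound / cond$protein_molar,
    dissociation_NO_displacement = (traj$Br + traj$Bt) / cond$protein_molar)
  kinetic_trace(times = traj$time, signal = sig, conditions = cond)
}

#' Apparent association rate constants from the microscopic rates
#'
#' Entry into the protein commits to binding with branching probability
#' `kg/(kg + kout)`, giving the closed forms
#' `k_ON,r = kin_r * kg_r / (kg_r + kout)` and analogously for t.
#'
#' @param rates a [rate_set()].
#' @return Named vector `c(kon_r, kon_t)` in M^-1 s^-1.
#' @export
#' @examples
#' derived_kon(mapgb_rates("solution"))  # ~2.1e7, ~1.1e6
derived_kon <- function(rates) {
  k <- unclass(rates)
  c(kon_r = k[["kin_r"]] * k[["kg_r"]] / (k[["kg_r"]] + k[["kout"]]),
    kon_t = k[["kin_t"]] * k[["kg_t"]] / (k[["kg_t"]] + k[["kout"]]))
}

#' Apparent dissociation rate constants from the microscopic rates
#'
#' A thermally broken Fe-CO bond only registers as dissociation if the
#' ligand escapes before geminate recapture:
#' `k_OFF = kdiss * kout / (kout + kg)` per conformation.
#'
#' @param rates a [rate_set()].
#' @return Named vector `c(koff_r, koff_t)` in s^-1.
#' @export
#' @examples
#' derived_koff(mapgb_rates("solution"))  # ~0.032, ~0.081
derived_koff <- function(rates) {
  k <- unclass(rates)
  c(koff_r = k[["kdiss_r"]] * k[["kout"]] / (k[["kout"]] + k[["kg_r"]]),
    koff_t = k[["kdiss_t"]] * k[["kout"]] / (k[["kout"]] + k[["kg_t"]]))
}

#' Conformational equilibrium constants and populations
#'
#' `K1`, `K2`, `K3` are the r-to-t equilibrium constants of the bound,
#' primary-docking-site and unliganded states.  The unliganded populations
#' follow from `K3`; the liganded ones from `K1`.  The predicted ratio of
#' the slow-rate to fast-rate amplitude in a two-phase dissociation
#' experiment equals `K1` (the liganded t/r population ratio).
#'
#' @param rates a [rate_set()].
#' @return List with `K1`, `K2`, `K3`, `unliganded` (named fractions
#'   `f_r`, `f_t`), `liganded` (`f_Br`, `f_Bt`), `amplitude_ratio`, and the
#'   `cycle_closure` diagnostic (ratio of the B_r->P_r->P_t->B_t->B_r cycle
#'   product to `K1`; 1 under detailed balance, which the published
#'   parameters do not enforce).
#' @export
equilibrium_summary <- function(rates) {
  k <- unclass(rates)
  K1 <- k[["k1"]] / k[["km1"]]
  K2 <- k[["k2"]] / k[["km2"]]
  K3 <- k[["k3"]] / k[["km3"]]
  # cycle B_r -> P_r -> P_t -> B_t -> B_r vs direct B_r -> B_t
  Kcycle <- (k[["kdiss_r"]] / k[["kg_r"]]) * K2 * (k[["kg_t"]] / k[["kdiss_t"]])
  list(K1 = K1, K2 = K2, K3 = K3,
       unliganded = c(f_r = 1 / (1 + K3), f_t = K3 / (1 + K3)),
       liganded = c(f_Br = 1 / (1 + K1), f_Bt = K1 / (1 + K1)),
       amplitude_ratio = K1,
       cycle_closure = Kcycle / K1)
}
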