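#' Experimental conditions for a simulated or measured kinetic trace
#'
#' Bundles everything the kinetic model needs to know about one experiment:
#' temperature, CO availability, the photolysed fraction and the
#' measurement mode.  Exactly one of `co_atm` (equilibration partial
#' pressure, converted to molarity by Henry's law) or `co_molar` must be
#' given.
#'
#' @param temperature_K absolute temperature (K); operating range 273-333 K.
#' @param co_atm CO partial pressure (atm), converted with
#'   [co_concentration()].
#' @param co_molar explicit CO concentration (mol/L); alternative to
#'   `co_atm`.
#' @param phi photolysis fraction in `[0, 1]` (flash mode only).
#' @param protein_molar total haem concentration (mol/L).
#' @param mode `"flash_photolysis"`, `"stopped_flow_association"` or
#'   `"dissociation_NO_displacement"`.
#' @param pseudo_first_order if `TRUE` the free-CO pool is held constant
#'   during integration.  Defaults to `TRUE` for flash photolysis (CO in
#'   large excess over haem) and `FALSE` otherwise.
#' @return An object of class `conditions` (a list).
#' @export
conditions <- function(temperature_K = 293.15,
                       co_atm = NULL, co_molar = NULL,
                       phi = 1, protein_molar = 50e-6,
                       mode = c("flash_photolysis",
                                "stopped_flow_association",
                                "dissociation_NO_displacement"),
                       pseudo_first_order = NULL) {
  mode <- match.arg(mode)
  if (temperature_K < 273 || temperature_K > 333)
    stop("temperature_K outside the 273-333 K operating range")
  if (is.null(co_atm) == is.null(co_molar) &&
      mode != "dissociation_NO_displacement")
    stop("give exactly one of co_atm or co_molar")
  if (mode == "dissociation_NO_displacement") {
    # NO scavenges every CO that reaches the solvent; the free pool is
    # irrelevant and pinned at zero
    co_atm <- NULL
    co_molar <- 0
  }
  if (!is.null(co_atm)) {
    if (co_atm < 0) stop("co_atm must be >= 0")
    co_molar <- co_concentration(co_atm, temperature_K)
  }
  if (co_molar < 0) stop("co_molar must be >= 0")
  if (mode == "flash_photolysis" && (is.na(phi) || is.null(phi)))
    stop("flash photolysis requires a photolysis fraction phi")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (protein_molar <= 0) stop("protein_molar must be > 0")
  if (is.null(pseudo_first_order))
    pseudo_first_order <- mode == "flash_photolysis"
  structure(list(temperature_K = temperature_K,
                 co_atm = co_atm,
                 co_molar = co_molar,
                 phi = phi,
                 protein_molar = protein_molar,
                 mode = mode,
                 pseudo_first_order = pseudo_first_order),
            class = "conditions")
}

#' @export
print.conditions <- function(x, ...) {
  cat("<conditions>", x$mode, "\n")
  cat(sprintf("  T = %.2f K, [CO] = %.3g M%s, phi = %.3g, [haem] = %.3g M\n",
              x$temperature_K, x$co_molar,
              if (!is.null(x$co_atm)) sprintf(" (%g atm)", x$co_atm) else "",
              x$phi, x$protein_molar))
  cat("  pseudo-first-order:", x$pseudo_first_order, "\n")
  invisible(x)
}

# Henry's-law solubility of CO in water, M/atm.  Literature values
# interpolated linearly; config-overridable through the `table` argument.
.co_henry_table <- data.frame(
  temperature_K = c(283.15, 288.15, 293.15, 298.15, 303.15, 308.15, 313.15),
  molar_per_atm = c(1.26e-3, 1.13e-3, 1.03e-3, 0.95e-3, 0.88e-3, 0.83e-3,
                    0.78e-3))

#' Equilibrium CO concentration from partial pressure
#'
#' Linear Henry's-law conversion using a built-in solubility table for CO
#' in water (1.03e-3 M/atm at 293.15 K), linearly interpolated over
#' 283-313 K.
#'
#' @param pressure_atm CO partial pressure (atm), `>= 0`.
#' @param temperature_K temperature (K) within the table range.
#' @param table optional replacement solubility table (columns
#'   `temperature_K`, `molar_per_atm`).
#' @return CO concentration in mol/L.
#' @export
#' @examples
#' co_concentration(1, 293.15)    # 1.03e-3
#' co_concentration(0.1, 293.15)  # 1.03e-4
co_concentration <- function(pressure_atm, temperature_K = 293.15,
                             table = NULL) {
  if (any(pressure_atm < 0)) stop("pressure_atm must be >= 0")
  if (is.null(table)) table <- .co_henry_table
  rng <- range(table$temperature_K)
  if (temperature_K < rng[1] || temperature_K > rng[2])
    stop(sprintf("temperature %.2f K outside solubility table range %g-%g K",
                 temperature_K, rng[1], rng[2]))
  s <- stats::approx(table$temperature_K, table$molar_per_atm,
                     xout = temperature_K)$y
  pressure_atm * s
}
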