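#' Microscopic rate constants for the two-conformation reaction scheme
#'
#' A `rate_set` holds the 17 microscopic rate constants of the minimal
#' reaction network used throughout the package: a globin with a
#' fast-rebinding conformation (`r`) and a slow-rebinding conformation
#' (`t`), each with a bound state, a primary docking site, a secondary
#' docking site and an unliganded state in contact with solvent CO.
#'
#' Naming convention: `kX` (no `m`) is always the r-to-t direction of a
#' conformational exchange, `kmX` the t-to-r back reaction.
#'
#' @param k1,km1 bound-state conformational exchange r<->t (s^-1).
#' @param k2,km2 primary-docking-site exchange r<->t (s^-1).
#' @param k3,km3 unliganded exchange r<->t (s^-1).
#' @param kin_r,kin_t bimolecular entry from the solvent into the primary
#'   docking site (M^-1 s^-1).
#' @param kout exit from the primary docking site to the solvent (s^-1),
#'   shared by both conformations.
#' @param kg_r,kg_t geminate rebinding from the primary docking site to the
#'   bound state (s^-1).
#' @param kdiss_r,kdiss_t thermal Fe-CO bond dissociation into the primary
#'   docking site (s^-1).
#' @param kmig_r,kret_r primary -> secondary and secondary -> primary
#'   docking-site migration in the r conformation (s^-1).
#' @param kmig_t,kret_t the same migration rates in the t conformation
#'   (s^-1).
#' @return An object of class `rate_set`: a named numeric vector of the 17
#'   rates.
#' @seealso [mapgb_rates()] for the published parameter sets,
#'   [derived_kon()], [derived_koff()], [equilibrium_summary()].
#' @export
rate_set <- function(k1, km1, k2, km2, k3, km3,
                     kin_r, kin_t, kout,
                     kg_r, kg_t, kdiss_r, kdiss_t,
                     kmig_r, kret_r, kmig_t, kret_t) {
  k <- c(k1 = k1, km1 = km1, k2 = k2, km2 = km2, k3 = k3, km3 = km3,
         kin_r = kin_r, kin_t = kin_t, kout = kout,
         kg_r = kg_r, kg_t = kg_t, kdiss_r = kdiss_r, kdiss_t = kdiss_t,
         kmig_r = kmig_r, kret_r = kret_r, kmig_t = kmig_t, kret_t = kret_t)
  validate_rate_set(k)
  structure(k, class = "rate_set")
}

#' @rdname rate_set
#' @param x numeric vector or list with the 17 rate names.
#' @export
as_rate_set <- function(x) {
  x <- unlist(x)
  miss <- setdiff(rate_names(), names(x))
  if (length(miss))
    stop("missing rate constants: ", paste(miss, collapse = ", "))
  k <- x[rate_names()]
  validate_rate_set(k)
  structure(k, class = "rate_set")
}

rate_names <- function() {
  c("k1", "km1", "k2", "km2", "k3", "km3",
    "kin_r", "kin_t", "kout",
    "kg_r", "kg_t", "kdiss_r", "kdiss_t",
    "kmig_r", "kret_r", "kmig_t", "kret_t")
}

validate_rate_set <- function(k) {
  if (length(k) != 17L || !is.numeric(k))
    stop("a rate_set needs the 17 named microscopic rate constants")
  bad <- !is.finite(k) | k < 0
  if (any(bad))
    stop("non-finite or negative rate constants: ",
         paste(names(k)[bad], collapse = ", "))
  # zero is tolerated only because limiting cases (disabled channels) are
  # legitimate model probes; published sets are strictly positive
  invisible(k)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> 17 microscopic rate constants\n")
  m <- matrix(unclass(x), ncol = 1,
              dimnames = list(names(x), "value"))
  print(format(m[, 1], digits = 4, scientific = TRUE), quote = FALSE)
  invisible(x)
}

#' Published rate constants for M. acetivorans protoglobin
#'
#' Returns the microscopic rate constants determined at 20 degrees C by
#' global analysis of CO flash-photolysis data for the protoglobin mutant
#' MaPgb* under three conditions: free in solution, encapsulated in silica
#' gel in the CO-bound state (`"co_gel"`, traps the fast-rebinding r
#' conformation) and encapsulated unliganded with CO added afterwards
#' (`"deoxy_gel"`, traps the slow-rebinding t conformation).
#'
#' @param condition one of `"solution"`, `"co_gel"`, `"deoxy_gel"`.
#' @return A [rate_set()].
#' @export
#' @examples
#' mapgb_rates("solution")
#' equilibrium_summary(mapgb_rates("deoxy_gel"))$K3   # 4.4
mapgb_rates <- function(condition = c("solution", "co_gel", "deoxy_gel")) {
  condition <- match.arg(condition)
  switch(condition,
    solution = rate_set(
      k1 = 1.35e5, km1 = 4.55e5,
      k2 = 0.6e5,  km2 = 2.5e4,
      k3 = 0.6e5,  km3 = 2.0e4,
      kin_r = 7.8e7, kin_t = 3.0e7, kout = 1.5e8,
      kg_r = 5.5e7, kg_t = 6.0e6,
      kdiss_r = 4.4e-2, kdiss_t = 8.4e-2,
      kmig_r = 1e7, kret_r = 1e7, kmig_t = 1e7, kret_t = 1e7),
    co_gel = rate_set(
      k1 = 1.35e5, km1 = 4.55e5,
      k2 = 0.4e5,  km2 = 1.4e4,
      k3 = 0.4e5,  km3 = 1.4e4,
      kin_r = 7.2e7, kin_t = 1.0e7, kout = 1.4e8,
      kg_r = 5.3e7, kg_t = 3.8e6,
      kdiss_r = 4.4e-2, kdiss_t = 8.3e-2,
      kmig_r = 1e7, kret_r = 0.7e7, kmig_t = 1e7, kret_t = 0.7e7),
    deoxy_gel = rate_set(
      k1 = 1.35e5, km1 = 4.5e5,
      k2 = 1.0e5,  km2 = 2.5e4,
      k3 = 1.1e5,  km3 = 2.5e4,
      kin_r = 6.9e7, kin_t = 1.0e7, kout = 1.0e8,
      kg_r = 3.8e7, kg_t = 3.8e6,
      kdiss_r = 4.4e-2, kdiss_t = 8.4e-2,
      kmig_r = 1e7, kret_r = 0.9e7, kmig_t = 0.6e7, kret_t = 1.1e7)
  )
}

#' Read or write a rate set as a flat YAML key-value file
#'
#' @param path file path.
#' @return `read_rates()` returns a [rate_set()]; `write_rates()` returns
#'   `path` invisibly.
#' @export
read_rates <- function(path) {
  as_rate_set(yaml::read_yaml(path))
}

#' @rdname read_rates
#' @param rates a [rate_set()].
#' @export
write_rates <- function(rates, path) {
  yaml::write_yaml(as.list(unclass(rates)), path)
  invisible(path)
}
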