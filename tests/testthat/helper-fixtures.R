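# Shared fixtures: published rate sets, standard conditions and a
# generator of random positive rate sets for property-style tests.

solution_rates <- function() mapgb_rates("solution")

flash_cond <- function(co_atm = 1, phi = 1, temperature_K = 293.15) {
  conditions(temperature_K = temperature_K, co_atm = co_atm, phi = phi,
             mode = "flash_photolysis")
}

# log-uniform random rate set; second-order entry rates kept in a range
# where k*C is numerically comparable to the first-order rates
random_rate_set <- function() {
  k <- 10^stats::runif(17, 1, 8)
  names(k) <- c("k1", "km1", "k2", "km2", "k3", "km3",
                "kin_r", "kin_t", "kout",
                "kg_r", "kg_t", "kdiss_r", "kdiss_t",
                "kmig_r", "kret_r", "kmig_t", "kret_t")
  k["kin_r"] <- 10^stats::runif(1, 5, 9)
  k["kin_t"] <- 10^stats::runif(1, 5, 9)
  as_rate_set(k)
}

# independent linear-algebra oracle: eigen-decomposition solution of the
# pseudo-first-order system dx/dt = A x
expm_solution <- function(rates, cond, times) {
  A <- rate_matrix(rates, cond$co_molar)
  y0 <- initial_state(cond, rates)[1:8]
  e <- eigen(A)
  c0 <- solve(e$vectors, y0)
  out <- t(vapply(times, function(t)
    Re(e$vectors %*% (c0 * exp(e$values * t)))[, 1], numeric(8)))
  colnames(out) <- names(y0)
  out
}

protein_total <- function(traj) {
  rowSums(traj[, c("Br", "Bt", "Pr", "Pt", "Sr", "St", "Ur", "Ut")])
}
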