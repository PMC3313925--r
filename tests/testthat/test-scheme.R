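test_that("rhs vanishes for a pure bound state with dissociation off", {
  k <- unclass(solution_rates())
  k[c("kdiss_r", "kdiss_t", "k1", "km1")] <- 0
  rs <- as_rate_set(k)
  state <- setNames(numeric(9), c("Br", "Bt", "Pr", "Pt", "Sr", "St",
                                  "Ur", "Ut", "C"))
  state["Br"] <- 50e-6
  expect_equal(unname(ode_rhs(state, rs)), rep(0, 9))
})

test_that("protein derivatives sum to zero for arbitrary states and rates", {
  set.seed(7)
  for (i in 1:25) {
    rs <- random_rate_set()
    state <- setNames(runif(9, 0, 1e-4), c("Br", "Bt", "Pr", "Pt", "Sr",
                                           "St", "Ur", "Ut", "C"))
    d <- ode_rhs(state, rs, pseudo_first_order = sample(c(TRUE, FALSE), 1))
    expect_lt(abs(sum(d[1:8])), 1e-12 * max(abs(d)))
  }
})

test_that("rhs rejects negative concentrations", {
  state <- setNames(c(-1e-6, rep(1e-6, 8)), c("Br", "Bt", "Pr", "Pt", "Sr",
                                              "St", "Ur", "Ut", "C"))
  expect_error(ode_rhs(state, solution_rates()), "non-negative")
})

test_that("isolated unliganded exchange equilibrates at K3 = 3", {
  rs <- solution_rates()  # k3 = 0.6e5, km3 = 2.0e4
  state <- setNames(numeric(9), c("Br", "Bt", "Pr", "Pt", "Sr", "St",
                                  "Ur", "Ut", "C"))
  state["Ur"] <- 1; state["Ut"] <- 3   # Ut/Ur = K3
  d <- ode_rhs(state, rs)
  expect_equal(unname(d["Ur"]), 0)
  expect_equal(unname(d["Ut"]), 0)
})

test_that("flash initial state splits the photoproduct 77/23 between r and t", {
  cond <- flash_cond(phi = 1)
  s <- initial_state(cond, solution_rates())
  expect_equal(unname(s["Pr"] / cond$protein_molar), 4.55 / 5.9,
               tolerance = 1e-12)
  expect_equal(unname(s["Pt"] / cond$protein_molar), 1.35 / 5.9,
               tolerance = 1e-12)
  expect_equal(unname(s["Br"] + s["Bt"]), 0)
})

test_that("stopped-flow initial state puts 25%/75% in the fast/slow conformer", {
  cond <- conditions(co_molar = 25e-6, protein_molar = 5e-6,
                     mode = "stopped_flow_association")
  s <- initial_state(cond, solution_rates())
  expect_equal(unname(s["Ur"] / cond$protein_molar), 0.25)
  expect_equal(unname(s["Ut"] / cond$protein_molar), 0.75)
})

test_that("unphotolysed sample stays bound apart from slow thermal dissociation", {
  cond <- flash_cond(phi = 0)
  rs <- solution_rates()
  s <- initial_state(cond, rs)
  expect_equal(unname(s["Br"] + s["Bt"]), cond$protein_molar)
  times <- log_time_grid(1e-8, 1e-3, 25)
  tr <- observable(integrate_scheme(rs, cond, times), cond)
  # the floor is the equilibrium unbound fraction ~ k_OFF/(k_ON [CO]),
  # a few 1e-6 at 1 atm
  expect_lt(max(tr$signal), 1e-5)
})

test_that("stiff integration matches the eigen-solution oracle on random rate sets", {
  cond <- flash_cond()
  times <- log_time_grid(1e-9, 1e-2, 30)
  set.seed(11)
  for (i in 1:100) {
    rs <- random_rate_set()
    sim <- as.matrix(integrate_scheme(rs, cond, times)[, 2:9])
    oracle <- expm_solution(rs, cond, times)
    scale <- max(abs(oracle))
    expect_lt(max(abs(sim - oracle)) / scale, 1e-6)
  }
})

test_that("protein is conserved to 1e-9 relative in every mode", {
  rs <- solution_rates()
  conds <- list(
    flash_cond(),
    conditions(co_molar = 25e-6, protein_molar = 5e-6,
               mode = "stopped_flow_association"),
    conditions(protein_molar = 5e-6, mode = "dissociation_NO_displacement"))
  grids <- list(log_time_grid(1e-9, 1e-2, 40),
                log_time_grid(1e-4, 10, 40),
                log_time_grid(1e-3, 100, 40))
  for (i in seq_along(conds)) {
    traj <- integrate_scheme(rs, conds[[i]], grids[[i]])
    rel <- abs(protein_total(traj) - conds[[i]]$protein_molar) /
      conds[[i]]$protein_molar
    expect_lt(max(rel), 1e-9)
  }
})

test_that("total CO is conserved under mass action", {
  rs <- solution_rates()
  cond <- conditions(co_molar = 25e-6, protein_molar = 5e-6,
                     mode = "stopped_flow_association",
                     pseudo_first_order = FALSE)
  traj <- integrate_scheme(rs, cond, log_time_grid(1e-4, 10, 30))
  co_tot <- traj$Br + traj$Bt + traj$Pr + traj$Pt + traj$Sr + traj$St + traj$C
  expect_lt(max(abs(co_tot - co_tot[1])) / co_tot[1], 1e-9)
})

test_that("the fully rebound steady state leaves under 1% of protein unbound at 1 atm", {
  rs <- solution_rates()
  cond <- flash_cond()
  # algebraic steady state: null space of the pseudo-first-order rate matrix
  A <- rate_matrix(rs, cond$co_molar)
  ns <- svd(A)$v[, 8]
  ns <- ns / sum(ns)
  expect_true(all(ns > -1e-12))
  unbound <- sum(ns[3:8])
  expect_lt(unbound, 0.01)
  # and the integrator reaches it
  traj <- integrate_scheme(rs, cond, c(1, 10, 100))
  frac <- (protein_total(traj) - traj$Br - traj$Bt) / cond$protein_molar
  expect_lt(frac[3], 0.01)
  expect_equal((traj$Br + traj$Bt)[3] / cond$protein_molar,
               ns[1] + ns[2], tolerance = 1e-4)
})

test_that("flash observable starts near 1 and the geminate phase completes by 100 ns", {
  rs <- solution_rates()
  cond <- flash_cond()
  times <- log_time_grid(1e-9, 1e-2, 120)
  N <- observable(integrate_scheme(rs, cond, times), cond)
  expect_gte(N$signal[1], 0.95)
  # geminate amplitude is spent before 100 ns: the signal is nearly flat
  # between 100 ns and 1 us, before bimolecular rebinding sets in
  i1 <- which.min(abs(N$time - 1e-7)); i2 <- which.min(abs(N$time - 1e-6))
  expect_lt(N$signal[i1] - N$signal[i2], 0.03)
})

test_that("dissociation observable starts at a fully bound signal of 1", {
  rs <- solution_rates()
  cond <- conditions(protein_molar = 5e-6,
                     mode = "dissociation_NO_displacement")
  tr <- observable(integrate_scheme(rs, cond, c(1e-6, 1e-3)), cond)
  expect_equal(tr$signal[1], 1, tolerance = 1e-6)
})

test_that("lowering CO slows bimolecular rebinding at every time past 1 us", {
  rs <- solution_rates()
  times <- log_time_grid(1e-6, 1e-2, 50)
  N1 <- observable(integrate_scheme(rs, flash_cond(co_atm = 1), times),
                   flash_cond(co_atm = 1))
  N01 <- observable(integrate_scheme(rs, flash_cond(co_atm = 0.1), times),
                    flash_cond(co_atm = 0.1))
  expect_true(all(N01$signal >= N1$signal - 1e-9))
})

test_that("raising kout monotonically increases the unbound fraction at 100 ns", {
  base <- unclass(solution_rates())
  vals <- vapply(c(0.5e8, 1.5e8, 4.5e8, 13.5e8), function(ko) {
    k <- base; k[["kout"]] <- ko
    cond <- flash_cond()
    observable(integrate_scheme(as_rate_set(k), cond, c(1e-7)), cond)$signal
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("with all conformational exchange off the branches evolve independently", {
  k <- unclass(solution_rates())
  k[c("k2", "km2", "k3", "km3")] <- 0
  # keep the bound-state ratio that sets the photoproduct split, but make
  # the exchange itself negligibly slow (zero would leave the split 0/0)
  k[c("k1", "km1")] <- k[c("k1", "km1")] * 1e-17
  rs <- as_rate_set(k)
  cond <- flash_cond()
  times <- log_time_grid(1e-9, 1e-2, 40)
  full <- observable(integrate_scheme(rs, cond, times), cond)

  # single-conformation sub-schemes: park the whole population in one branch
  # by instant photolysis of a pure-r (or pure-t) bound ensemble
  single <- function(branch) {
    kk <- k
    if (branch == "r") { kk[["k1"]] <- 0; kk[["km1"]] <- 1 }
    else { kk[["k1"]] <- 1; kk[["km1"]] <- 0 }
    # k3/km3 stay 0 so U does not exchange; initial split is set by k1/km1
    rr <- as_rate_set(kk)
    observable(integrate_scheme(rr, cond, times), cond)$signal
  }
  fBr <- 4.55 / 5.9; fBt <- 1.35 / 5.9
  mix <- fBr * single("r") + fBt * single("t")
  expect_lt(max(abs(full$signal - mix)), 1e-8)
})

test_that("the slow-rebinding branch peaks at 40-50% occupancy after photolysis", {
  occ <- t_branch_peak_occupancy(solution_rates())
  expect_gte(occ, 0.35)
  expect_lte(occ, 0.55)
})

test_that("closed-form association rates reproduce the published values", {
  kon <- derived_kon(solution_rates())
  expect_equal(unname(kon["kon_r"]), 2.1e7, tolerance = 0.005)
  expect_equal(unname(kon["kon_t"]), 1.1e6, tolerance = 0.05)
  # with no escape, entry always converts to binding
  k <- unclass(solution_rates()); k[["kout"]] <- 0
  expect_equal(unname(derived_kon(as_rate_set(k))["kon_r"]), k[["kin_r"]])
})

test_that("closed-form dissociation rates reproduce the published values", {
  koff <- derived_koff(solution_rates())
  expect_equal(unname(koff["koff_r"]), 0.032, tolerance = 0.01)
  expect_equal(unname(koff["koff_t"]), 0.081, tolerance = 0.005)
  # with no geminate recapture every broken bond dissociates
  k <- unclass(solution_rates()); k[c("kg_r", "kg_t")] <- 0
  expect_equal(unname(derived_koff(as_rate_set(k))),
               unname(k[c("kdiss_r", "kdiss_t")]))
})

test_that("equilibrium summary reproduces the published constants and populations", {
  eq <- equilibrium_summary(solution_rates())
  expect_equal(eq$K3, 3.0)
  expect_equal(eq$K2, 2.4)
  expect_equal(eq$K1, 0.3, tolerance = 0.02)
  expect_equal(unname(eq$unliganded["f_t"]), 0.75)
  expect_equal(eq$amplitude_ratio, eq$K1)
  expect_equal(equilibrium_summary(mapgb_rates("deoxy_gel"))$K3, 4.4)
  expect_equal(equilibrium_summary(mapgb_rates("co_gel"))$K3, 2.857,
               tolerance = 0.001)
  # the published rates do not close the thermodynamic cycle
  expect_equal(eq$cycle_closure, 0.46, tolerance = 0.02)
})

test_that("rate set validation rejects malformed input", {
  expect_error(as_rate_set(c(k1 = 1)), "missing")
  k <- unclass(solution_rates()); k[["kg_r"]] <- -1
  expect_error(as_rate_set(k), "negative")
  expect_error(conditions(temperature_K = 400), "operating range")
  expect_error(conditions(co_atm = 1, co_molar = 1e-3), "exactly one")
  expect_error(conditions(co_atm = 1, phi = 2), "phi")
})
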