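test_that("a single exponential fitted with two components leaves one degenerate", {
  times <- log_time_grid(1e-6, 1e-2, 80)
  tr <- kinetic_trace(times, multiexp_curve(times, 1, 1e-4))
  fit <- fit_multiexponential(tr, n_components = 2, offset = FALSE)
  expect_true(fit$converged)
  expect_lt(min(fit$components$fraction), 1e-6)
  dom <- which.max(fit$components$fraction)
  expect_equal(fit$components$tau[dom], 1e-4, tolerance = 1e-6)
})

test_that("biexponential lifetimes are recovered within 5% under noise", {
  times <- log_time_grid(1e-7, 1e-1, 150)
  y <- multiexp_curve(times, c(0.4, 0.6), c(1e-5, 1e-3))
  n_ok <- 0L
  for (s in 1:100) {
    set.seed(s)
    tr <- kinetic_trace(times, y + rnorm(length(y), sd = 0.002))
    fit <- fit_multiexponential(tr, n_components = 2, offset = TRUE)
    ok <- abs(fit$components$tau[1] / 1e-5 - 1) < 0.05 &&
      abs(fit$components$tau[2] / 1e-3 - 1) < 0.05
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok, 95L)
})

test_that("lifetimes are reported sorted with fractional amplitudes", {
  times <- log_time_grid(1e-7, 1e-1, 120)
  set.seed(2)
  tr <- kinetic_trace(times, multiexp_curve(times, c(0.6, 0.4),
                                            c(1e-3, 1e-5)) +
                        rnorm(120, sd = 1e-3))
  fit <- fit_multiexponential(tr, n_components = 2, offset = TRUE)
  expect_true(all(diff(fit$components$tau) > 0))
  expect_equal(sum(fit$components$fraction), 1)
})

test_that("the three-component stretched relaxation is recovered from noisy data", {
  rec <- relaxation_component_recovery(seed = 3)
  expect_equal(rec$tau2_us, 99, tolerance = 0.1)
  expect_gt(rec$beta2, 0.3); expect_lt(rec$beta2, 0.7)
  expect_gt(rec$beta3, 0.9)   # the slowest decay is not stretched
})

test_that("stretched exponents respect their bounds", {
  times <- log_time_grid(1e-7, 1e-1, 100)
  set.seed(4)
  tr <- kinetic_trace(times, multiexp_curve(times, 1, 1e-4, 0.5) +
                        rnorm(100, sd = 1e-3))
  fit <- fit_multiexponential(tr, n_components = 1, stretched = TRUE)
  expect_gte(fit$components$beta, 0.2)
  expect_lte(fit$components$beta, 1)
  expect_equal(fit$components$beta, 0.5, tolerance = 0.05)
})

test_that("k_obs regression recovers exact and closed-form slopes", {
  co <- c(5, 10, 25, 50, 100) * 1e-6
  # exact linear input
  res <- kobs_vs_concentration(co, 2e7 * co + 3)
  expect_equal(res$slope, 2e7, tolerance = 1e-12)
  expect_equal(res$intercept, 3, tolerance = 1e-9)
  # rates generated from the closed-form association constant
  kon <- derived_kon(solution_rates())[["kon_r"]]
  res2 <- kobs_vs_concentration(co, kon * co)
  expect_equal(res2$slope, kon, tolerance = 1e-6)
  expect_lt(abs(res2$intercept), 1e-9)
  expect_error(kobs_vs_concentration(co[1:2], c(1, 2)), "at least 3")
})

test_that("self-fit started at truth stays at truth with chi-square at the noise floor", {
  rs <- solution_rates()
  tr1 <- make_flash_trace(rs, flash_cond(co_atm = 1), n_points = 80,
                          sigma = 0.002, seed = 21)
  tr2 <- make_flash_trace(rs, flash_cond(co_atm = 0.1), n_points = 80,
                          sigma = 0.002, seed = 22)
  spec <- fit_spec(list(tr1, tr2), rs, max_iter = 40)
  fit <- global_fit(spec)
  n <- nrow(tr1) + nrow(tr2)
  expect_lt(fit$chisq, n + 4 * sqrt(2 * n))
  rel <- unclass(fit$rates)[spec$free] / unclass(rs)[spec$free]
  expect_true(all(abs(rel - 1) < 0.05))
  # fixed-mask parameters return bit-identical
  fixed <- setdiff(names(unclass(rs)), spec$free)
  expect_identical(unclass(fit$rates)[fixed], unclass(rs)[fixed])
})

test_that("the objective is invariant under dataset reordering", {
  rs <- solution_rates()
  tr1 <- make_flash_trace(rs, flash_cond(co_atm = 1), n_points = 50,
                          sigma = 0.002, seed = 31)
  tr2 <- make_flash_trace(rs, flash_cond(co_atm = 0.1), n_points = 50,
                          sigma = 0.002, seed = 32)
  # zero iterations: evaluate the objective at the starting rates only
  f12 <- suppressWarnings(global_fit(fit_spec(list(tr1, tr2), rs,
                                              max_iter = 0)))
  f21 <- suppressWarnings(global_fit(fit_spec(list(tr2, tr1), rs,
                                              max_iter = 0)))
  expect_equal(f12$chisq, f21$chisq, tolerance = 1e-12)
})

test_that("a second CO concentration is what makes kin_t identifiable", {
  rs <- solution_rates()
  tr1 <- make_flash_trace(rs, flash_cond(co_atm = 1), n_points = 100,
                          sigma = 0.002, seed = 41)
  tr2 <- make_flash_trace(rs, flash_cond(co_atm = 0.1), n_points = 100,
                          sigma = 0.002, seed = 42)
  one <- global_fit(fit_spec(list(tr1), rs, max_iter = 30))
  both <- global_fit(fit_spec(list(tr1, tr2), rs, max_iter = 30))
  # the t-branch entry rate is poorly constrained by a single
  # concentration; the 0.1 atm trace tightens it several-fold
  expect_gt(one$rel_se[["kin_t"]], 2 * both$rel_se[["kin_t"]])
  expect_gt(one$rel_se[["kin_t"]], 0.15)
})
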