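single_state_truth <- function(j = 100, a = 0, b = 0, noise_sd = 0,
                               c0 = 100, end = 400, tau = 0, seed = 1) {
  simulation_truth(
    fluxes = list(ROUTINE = j),
    schedule = tibble::tibble(time_s = numeric(), reagent = character()),
    chamber = chamber_config(volume_ml = 2, cell_mio = 2,
                             background_a = a, background_b = b),
    transition_tau = tau, noise_sd = noise_sd, initial_o2 = c0,
    end_time_s = end, seed = seed
  )
}

bare_protocol <- function() {
  protocol_definition(
    "BARE", tibble::tibble(reagent = character(), state = character()),
    reference_state = "ROUTINE"
  )
}

test_that("a constant state with no background decays linearly", {
  # rho = 1, j = 100 pmol/(s*1e6): dC/dt = -0.1 uM/s
  run <- simulate_run(single_state_truth(), bare_protocol())
  expect_equal(run$trace$o2_um, 100 - 0.1 * run$trace$time_s,
               tolerance = 1e-7)
})

test_that("oxygen-dependent background follows the linear-ODE closed form", {
  # dC/dt = -(rho*j + a + b*C)/1000; constant j: C* + (C0 - C*) e^(-b t/1000)
  j <- 80; a <- 2; b <- 1.5
  run <- simulate_run(single_state_truth(j = j, a = a, b = b),
                      bare_protocol())
  rho <- 1
  c_star <- -(rho * j + a) / b
  oracle <- c_star + (100 - c_star) * exp(-b * run$trace$time_s / 1000)
  expect_equal(run$trace$o2_um, oracle, tolerance = 1e-6)
})

test_that("mass balance: consumed oxygen equals the integrated respiration", {
  tr <- hrr_preset("control", noise_sd = 0)
  tr$chamber$background_a <- 0
  tr$chamber$background_b <- 0
  run <- simulate_run(tr, builtin_protocol("SUIT_MAIN"))
  t <- run$trace$time_s
  # integrate the exact forcing: piecewise exponential approach to plateaus
  bounds <- c(0, tr$schedule$time_s, tr$end_time_s)
  targets <- hrrflux:::interval_targets(tr, builtin_protocol("SUIT_MAIN"))
  tau <- tr$transition_tau
  total <- 0; v <- targets[1]
  for (k in seq_along(targets)) {
    dt <- bounds[k + 1] - bounds[k]
    total <- total + targets[k] * dt +
      (v - targets[k]) * tau * (1 - exp(-dt / tau))
    v <- targets[k] + (v - targets[k]) * exp(-dt / tau)
  }
  rho <- tr$chamber$cell_mio / tr$chamber$volume_ml
  consumed <- run$trace$o2_um[1] - run$trace$o2_um[length(t)]
  expect_equal(consumed, rho * total / 1000, tolerance = 1e-6)
})

test_that("simulation is bit-reproducible given its seed", {
  tr <- hrr_preset("control", seed = 123)
  r1 <- simulate_run(tr, builtin_protocol("SUIT_MAIN"))
  r2 <- simulate_run(tr, builtin_protocol("SUIT_MAIN"))
  expect_identical(r1$trace$o2_um, r2$trace$o2_um)
  tr2 <- hrr_preset("control", seed = 124)
  r3 <- simulate_run(tr2, builtin_protocol("SUIT_MAIN"))
  expect_false(identical(r1$trace$o2_um, r3$trace$o2_um))
})

test_that("presets reproduce the anchored ratio structure through the full pipeline", {
  ctl <- state_fluxes(simulate_run(hrr_preset("control", noise_sd = 0),
                                   builtin_protocol("SUIT_MAIN")))
  trt <- state_fluxes(simulate_run(hrr_preset("mpp_treated", noise_sd = 0),
                                   builtin_protocol("SUIT_MAIN")))
  expect_equal(fcr(ctl, "LEAK"), 0.19, tolerance = 0.01 / 0.19)
  expect_equal(fcr(trt, "LEAK"), 0.31, tolerance = 0.01 / 0.31)
  expect_equal(coupling_efficiency(ctl, "OXPHOS"), 0.78, tolerance = 1e-3)
  expect_equal(coupling_efficiency(trt, "OXPHOS"), 0.65, tolerance = 1e-3)
  # treated uncoupled capacity down ~63%
  ets_drop <- percent_change(
    ctl$rox_corrected_flux[ctl$state == "ETS"],
    trt$rox_corrected_flux[trt$state == "ETS"]
  )
  expect_equal(ets_drop, -62.7, tolerance = 0.01)
  expect_error(hrr_preset("x"), "control, mpp_treated")
})

test_that("cohorts are seeded, reproducible, and ratio-preserving", {
  runs <- simulate_cohort("control", 5, between_run_cv = 0,
                          state_jitter_cv = 0, seed = 5)
  truths <- lapply(runs, attr, "truth")
  # cv = 0, jitter = 0: identical truth, different noise realizations
  for (i in 2:5) {
    expect_equal(truths[[i]]$fluxes, truths[[1]]$fluxes)
    expect_false(identical(runs[[i]]$trace$o2_um, runs[[1]]$trace$o2_um))
  }
  runs_again <- simulate_cohort("control", 5, between_run_cv = 0,
                                state_jitter_cv = 0, seed = 5)
  expect_identical(runs[[3]]$trace$o2_um, runs_again[[3]]$trace$o2_um)

  # joint lognormal scaling preserves every truth ratio
  runs_cv <- simulate_cohort("control", 4, between_run_cv = 0.15,
                             state_jitter_cv = 0, seed = 6)
  for (run in runs_cv) {
    fl <- attr(run, "truth")$fluxes
    corr <- function(s) max(fl[[s]]) - fl$ROX
    expect_equal(corr("LEAK") / corr("ETS"), 0.19, tolerance = 1e-10)
    expect_equal(corr("OXPHOS") / corr("ETS"), 19 / 0.22 / 100,
                 tolerance = 1e-10)
  }
})

test_that("oxygen depletion floors the trace and attaches a warning diagnostic", {
  tr <- single_state_truth(j = 400, c0 = 50, end = 400)
  expect_warning(run <- simulate_run(tr, bare_protocol()), "depleted")
  expect_true(all(run$trace$o2_um >= 0))
  d <- attr(run, "diagnostics")
  expect_identical(d$severity, "warning")
})
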