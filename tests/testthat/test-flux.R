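test_that("derive_flux recovers analytic derivatives", {
  t <- seq(0, 300, 2)
  # linear decay: slope -0.1 uM/s -> 100 pmol/(s*mL) everywhere
  tr <- oxygen_trace(t, 100 - 0.1 * t)
  for (m in c("sliding-regression", "savitzky-golay")) {
    fl <- derive_flux(tr, window_s = 20, method = m)
    expect_equal(fl$j_total, rep(100, length(t)), tolerance = 1e-8)
  }
  # constant concentration -> zero flux
  tr0 <- oxygen_trace(t, rep(150, length(t)))
  expect_equal(derive_flux(tr0, 20)$j_total, rep(0, length(t)),
               tolerance = 1e-10)
  # exponential decay, compare to closed-form derivative
  te <- seq(0, 2000, 1)
  tre <- oxygen_trace(te, 100 * exp(-0.001 * te))
  fle <- derive_flux(tre, window_s = 20)
  analytic <- 100 * 0.001 * exp(-0.001 * te) * 1000
  expect_lt(max(abs(fle$j_total - analytic) / analytic), 0.01)
})

test_that("derive_flux validates its window and never smooths across events", {
  t <- seq(0, 100, 2)
  tr <- oxygen_trace(t, 180 - 0.05 * t)
  expect_error(derive_flux(tr, window_s = 4), "at least 5 samples")

  # kinked decay: slopes -0.02 then -0.10 around an event at t = 150;
  # with the event as a break, both sides are recovered exactly
  tk <- linear_trace(c(-0.02, -0.10), breaks = 150, end_s = 300)
  fl <- derive_flux(tk, 20, break_times = 150)
  expect_equal(fl$j_total[tk$time_s < 150], rep(20, sum(tk$time_s < 150)),
               tolerance = 1e-8)
  expect_equal(fl$j_total[tk$time_s >= 150], rep(100, sum(tk$time_s >= 150)),
               tolerance = 1e-8)
  # without the break the estimates blur across the kink
  blur <- derive_flux(tk, 20)
  expect_gt(max(abs(blur$j_total[tk$time_s < 150] - 20)), 1)
})

test_that("background subtraction implements the linear-in-oxygen model", {
  t <- seq(0, 100, 2)
  tr <- oxygen_trace(t, rep(100, length(t)))
  fl <- derive_flux(tr, 20)
  fl$j_total <- rep(102, nrow(fl))

  ch0 <- chamber_config(cell_mio = 2, background_a = 0, background_b = 0)
  expect_equal(subtract_background(fl, tr, ch0)$j_sample, fl$j_total)

  ch_a <- chamber_config(cell_mio = 2, background_a = 2)
  expect_equal(subtract_background(fl, tr, ch_a)$j_sample,
               rep(100, nrow(fl)))

  ch_ab <- chamber_config(cell_mio = 2, background_a = 1, background_b = 0.01)
  expect_equal(fl$j_total - subtract_background(fl, tr, ch_ab)$j_sample,
               rep(2, nrow(fl))) # a + b*C = 1 + 0.01*100

  tr2 <- oxygen_trace(t + 1, rep(100, length(t)))
  expect_error(subtract_background(fl, tr2, ch0), "time grid")
})

test_that("per-cell normalization scales by volume over cell count", {
  t <- seq(0, 100, 2)
  tr <- oxygen_trace(t, rep(100, length(t)))
  fl <- derive_flux(tr, 20)
  fl$j_sample <- rep(100, nrow(fl))
  expect_equal(normalize_per_cells(fl, chamber_config(2, cell_mio = 2))$j_cell,
               rep(100, nrow(fl)))
  expect_equal(normalize_per_cells(fl, chamber_config(2, cell_mio = 1))$j_cell,
               rep(200, nrow(fl)))
  expect_equal(normalize_per_cells(fl, chamber_config(2, cell_mio = 4))$j_cell,
               rep(50, nrow(fl)))
  expect_error(chamber_config(2, cell_mio = 0), "> 0")
})

test_that("segment_states maps events to the documented state spans", {
  run <- step_run(default_step_fluxes())
  segs <- segment_states(run)
  expect_equal(
    segs$state,
    c("ROUTINE", "LEAK", "LEAK", "OXPHOS_CI", "OXPHOS", "ETS", "ETS",
      "ETS_CII", "ROX")
  )
  expect_equal(segs$t_start,
               c(0, 300, 600, 900, 1200, 1500, 1650, 1800, 2100))
  expect_equal(segs$t_end,
               c(300, 600, 900, 1200, 1500, 1650, 1800, 2100, 2400))
  expect_equal(segs$cccp_step[segs$state == "ETS"], c(1L, 2L))

  # rotenone-first protocol: no complex-I OXPHOS state is ever emitted
  cii_run <- simulate_run(hrr_preset("control", "SUIT_CII", noise_sd = 0),
                          builtin_protocol("SUIT_CII"))
  expect_false("OXPHOS_CI" %in% segment_states(cii_run)$state)

  # zero events under an eventless protocol: a single ROUTINE segment
  bare <- run_record(
    run$trace, titration_events(numeric(), character()),
    run$chamber,
    protocol_definition("BARE",
                        tibble::tibble(reagent = character(),
                                       state = character()),
                        reference_state = "ROUTINE")
  )
  segs0 <- segment_states(bare)
  expect_equal(segs0$state, "ROUTINE")
  expect_equal(c(segs0$t_start, segs0$t_end), range(run$trace$time_s))
})

test_that("mark_steady_state finds plateaus and validates segment length", {
  t <- seq(0, 600, 2)
  fl <- structure(
    tibble::tibble(time_s = t, j_total = NA_real_, j_sample = NA_real_,
                   j_cell = rep(42, length(t))),
    class = c("flux_series", "tbl_df", "tbl", "data.frame")
  )
  mk <- mark_steady_state(fl, list(state = "X", t_start = 0, t_end = 600))
  expect_equal(mk$mean_flux, 42)
  expect_equal(mk$sd_flux, 0)
  expect_gte(mk$n_points, 5)

  # exponential approach to a plateau: settling exclusion recovers J_inf
  j_inf <- 100
  fl$j_cell <- j_inf - 60 * exp(-t / 30)
  mk2 <- mark_steady_state(fl, list(state = "X", t_start = 0, t_end = 600),
                           settle_s = 120, window_s = 60)
  expect_lt(abs(mk2$mean_flux - j_inf) / j_inf, 0.01)

  expect_error(
    mark_steady_state(fl, list(state = "X", t_start = 0, t_end = 100),
                      settle_s = 60, window_s = 60),
    "smaller windows"
  )
})

test_that("state_fluxes recovers stepwise truth and applies the ROX and max-ETS rules", {
  truth <- default_step_fluxes()
  tab <- state_fluxes(step_run(truth))
  expect_s3_class(tab, "state_flux_tbl")

  # raw plateaus recovered (instantaneous steps, no background, no noise)
  expected_raw <- c(ROUTINE = 60, LEAK = 19, OXPHOS_CI = 70, OXPHOS = 100,
                    ETS = 120, ETS_CII = 45, ROX = 5)
  got <- setNames(tab$raw_flux, tab$state)[names(expected_raw)]
  expect_equal(got, expected_raw, tolerance = 1e-6)

  # ETS is the maximum over CCCP candidates (110 then 120 -> 120),
  # not the last step: check also with a declining titration
  expect_equal(got[["ETS"]], 120, tolerance = 1e-6)
  declining <- truth
  declining[["ETS1"]] <- 120
  declining[["ETS2"]] <- 110
  tab_dec <- state_fluxes(step_run(declining))
  expect_equal(tab_dec$raw_flux[tab_dec$state == "ETS"], 120,
               tolerance = 1e-6)

  # ROX correction: corrected = raw - ROX; corrected ROX exactly 0
  expect_identical(tab$rox_corrected_flux[tab$state == "ROX"], 0)
  expect_equal(tab$rox_corrected_flux[tab$state == "LEAK"], 14,
               tolerance = 1e-6)
  expect_equal(tab$rox_corrected_flux, tab$raw_flux - 5, tolerance = 1e-6)
})

test_that("state fluxes are linear in trace slopes and exactly cell-count invariant", {
  truth <- default_step_fluxes()
  tab1 <- state_fluxes(step_run(truth))
  tab2 <- state_fluxes(step_run(truth * 0.5))
  expect_equal(tab2$raw_flux, 0.5 * tab1$raw_flux, tolerance = 1e-8)

  # doubling cell count with the same trace halves every j_cell exactly
  run_half <- step_run(truth)
  run_half$chamber <- chamber_config(2, cell_mio = 4)
  tab_half <- state_fluxes(run_half)
  expect_equal(tab_half$raw_flux, tab1$raw_flux / 2, tolerance = 1e-12)
})
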