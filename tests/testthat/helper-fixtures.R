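# Fixtures built in code: no data files.

# A state-flux table assembled directly from corrected fluxes (plus a ROX
# level), bypassing the trace pipeline; used to test the metrics layer in
# isolation.
make_sft <- function(corrected, rox = 5, sample_id = "S1", group = "control") {
  states <- c(names(corrected), "ROX")
  raw <- c(unname(corrected) + rox, rox)
  out <- tibble::tibble(
    sample_id = sample_id, group = group, state = states,
    raw_flux = raw,
    rox_corrected_flux = c(unname(corrected), 0),
    t_start = NA_real_, t_end = NA_real_, sd_flux = 0, n_points = 30L
  )
  structure(out, class = c("state_flux_tbl", class(out)))
}

# Random plausible single-run table (all states), seeded.
random_sft <- function(seed, sample_id = "S1", group = "control") {
  set.seed(seed)
  ets <- runif(1, 40, 150)
  leak <- runif(1, 0.05, 0.5) * ets
  make_sft(
    c(ROUTINE = runif(1, leak, ets), LEAK = leak,
      OXPHOS_CI = runif(1, leak, ets), OXPHOS = runif(1, leak, 1.1 * ets),
      ETS = ets, ETS_CII = runif(1, 0.1, 0.6) * ets),
    rox = runif(1, 0, 10), sample_id = sample_id, group = group
  )
}

# Noise-free trace with piecewise-linear concentration decay: slope_j on
# segment j between consecutive break times.
linear_trace <- function(slopes_um_s, breaks, end_s, dt = 2, c0 = 180) {
  t <- seq(0, end_s, by = dt)
  seg <- findInterval(t, breaks)
  bounds <- c(0, breaks)
  conc <- numeric(length(t))
  level <- c0
  for (k in seq_along(slopes_um_s)) {
    idx <- which(seg == k - 1)
    conc[idx] <- level + slopes_um_s[k] * (t[idx] - bounds[k])
    nxt <- if (k < length(slopes_um_s)) bounds[k + 1] else end_s
    level <- level + slopes_um_s[k] * (nxt - bounds[k])
  }
  oxygen_trace(t, conc)
}

main_events <- function() {
  titration_events(
    c(300, 600, 900, 1200, 1500, 1650, 1800, 2100),
    c("DIG", "G", "ADP", "S", "CCCP", "CCCP", "ROT", "AMA")
  )
}

# Full synthetic run with stepwise-linear decay matching given j_cell raw
# plateaus (instantaneous transitions, no background, no noise).
step_run <- function(j_cell_raw, chamber = chamber_config(cell_mio = 2),
                     group = "control", sample_id = "S1") {
  ev <- main_events()
  states <- c("ROUTINE", "LEAK", "LEAK", "OXPHOS_CI", "OXPHOS", "ETS1",
              "ETS2", "ETS_CII", "ROX")
  rho <- chamber$cell_mio / chamber$volume_ml
  slopes <- -rho * j_cell_raw[states] / 1000
  tr <- linear_trace(unname(slopes), ev$time_s, 2400)
  attr(tr, "sample_id") <- sample_id
  run_record(tr, ev, chamber, builtin_protocol("SUIT_MAIN"), group = group)
}

default_step_fluxes <- function() {
  c(ROUTINE = 60, LEAK = 19, OXPHOS_CI = 70, OXPHOS = 100,
    ETS1 = 110, ETS2 = 120, ETS_CII = 45, ROX = 5)
}
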