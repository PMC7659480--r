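# SUIT state segmentation and steady-state plateau marking.

#' Segment a run into respiratory states
#'
#' Maps the titration events onto the protocol's state sequence. ROUTINE
#' spans acquisition start to the first event; every other state spans its
#' triggering event to the next event (or acquisition end). Consecutive
#' events entering the same state (glutamate during LEAK) give that state
#' several sub-segments; each uncoupler (CCCP) step gives an ETS candidate
#' sub-segment, numbered in `cccp_step`.
#'
#' @param run A [run_record()]; must pass [validate_run()] without errors.
#' @return A tibble with columns `state`, `t_start`, `t_end`, `sub_segment`,
#'   `cccp_step` (NA outside ETS candidates), one row per inter-event
#'   interval.
#' @export
segment_states <- function(run) {
  diags <- validate_run(run)
  errs <- diags$message[diags$severity == "error"]
  if (length(errs) > 0) {
    abort(paste0("run does not satisfy its protocol: ",
                 paste(errs, collapse = " ")))
  }
  tr <- run$trace
  ev <- run$events
  proto <- run$protocol
  ev <- ev[ev$reagent %in% proto$transitions$reagent, , drop = FALSE]

  bounds <- c(tr$time_s[1], ev$time_s, tr$time_s[nrow(tr)])
  states <- c("ROUTINE",
              proto$transitions$state[match(ev$reagent,
                                            proto$transitions$reagent)])
  out <- tibble::tibble(
    state = states,
    t_start = bounds[-length(bounds)],
    t_end = bounds[-1]
  )
  out <- out[out$t_end > out$t_start, , drop = FALSE]
  out <- dplyr::mutate(dplyr::group_by(out, .data$state),
                       sub_segment = dplyr::row_number())
  out <- dplyr::ungroup(out)
  out$cccp_step <- ifelse(out$state == "ETS", out$sub_segment, NA_integer_)
  out
}

#' Mark the steady-state plateau inside one state segment
#'
#' Slides a window of `window_s` seconds over the segment, excluding the
#' first `settle_s` seconds after the titration (mixing/response transient),
#' and returns the window minimizing the standard deviation of the
#' cell-specific flux. Ties break deterministically to the latest such
#' window. This formalizes the manual "mark" placed on a flux plateau.
#'
#' @param flux A `flux_series` with `j_cell` filled.
#' @param segment One row of [segment_states()] output (or any list with
#'   `state`, `t_start`, `t_end`).
#' @param settle_s Settling exclusion after the triggering event, seconds.
#' @param window_s Mark window length, seconds.
#' @return A one-row tibble: `state`, `t_start`, `t_end` (the chosen window),
#'   `mean_flux`, `sd_flux`, `n_points`.
#' @export
mark_steady_state <- function(flux, segment, settle_s = 60, window_s = 60) {
  stopifnot(inherits(flux, "flux_series"))
  if (all(is.na(flux$j_cell))) abort("`j_cell` not filled yet.")
  dur <- segment$t_end - segment$t_start
  if (dur <= settle_s + window_s) {
    abort(paste0(
      "segment ", segment$state, " (", round(dur), " s) is shorter than ",
      "settle_s + window_s (", settle_s + window_s,
      " s); use smaller windows."
    ))
  }
  t <- flux$time_s
  j <- flux$j_cell
  lo_t <- segment$t_start + settle_s
  hi_t <- segment$t_end
  cand <- which(t >= lo_t & t + window_s <= hi_t)
  if (length(cand) == 0) abort("no candidate window fits the segment.")

  # rolling mean/sd over [t_i, t_i + window_s] via prefix sums
  hi <- findInterval(t[cand] + window_s, t)
  lo <- cand
  S1 <- c(0, cumsum(j)); S2 <- c(0, cumsum(j * j))
  csum <- function(S, i, k) S[k + 1L] - S[i]
  n <- hi - lo + 1L
  if (any(n < 5L)) abort("mark window holds fewer than 5 samples.")
  mu <- csum(S1, lo, hi) / n
  v <- pmax(0, (csum(S2, lo, hi) - n * mu^2) / (n - 1))
  sdv <- sqrt(v)
  best <- max(which(sdv <= min(sdv) + 1e-12)) # latest window on ties
  tibble::tibble(
    state = segment$state,
    t_start = t[lo[best]], t_end = t[hi[best]],
    mean_flux = mu[best], sd_flux = sdv[best], n_points = n[best]
  )
}

#' Per-state oxygen fluxes for one run
#'
#' Composes the whole per-run pipeline: derivative, background subtraction,
#' per-cell normalization, state segmentation and plateau marking. For states
#' entered by several events (LEAK persisting through glutamate) the mark is
#' placed in the latest sub-segment; the ETS flux is the maximum mark over
#' the CCCP titration candidates (over-titration depresses the flux, so the
#' last step is not necessarily the optimum). All states are then corrected
#' for the residual oxygen consumption: `rox_corrected = raw - raw(ROX)`,
#' with the ROX state itself exactly 0. Negative corrected fluxes are kept
#' (clamping would bias every downstream ratio) and flagged with a warning.
#'
#' @param run A [run_record()].
#' @param settle_s,window_s Mark placement parameters, see
#'   [mark_steady_state()].
#' @param deriv_window_s,method Derivative parameters, see [derive_flux()].
#' @return A tibble of class `state_flux_tbl`, one row per state:
#'   `sample_id`, `group`, `state`, `raw_flux`, `rox_corrected_flux`
#'   (pmol/(s·10^6 cells)), `t_start`, `t_end`, `sd_flux`, `n_points`.
#' @export
state_fluxes <- function(run, settle_s = 60, window_s = 60,
                         deriv_window_s = 20, method = "sliding-regression") {
  segs <- segment_states(run) # also validates
  fl <- derive_flux(run$trace, window_s = deriv_window_s, method = method,
                    break_times = run$events$time_s)
  fl <- subtract_background(fl, run$trace, run$chamber)
  fl <- normalize_per_cells(fl, run$chamber)

  marks <- list()
  for (st in unique(segs$state)) {
    rows <- segs[segs$state == st, , drop = FALSE]
    if (st == "ETS") {
      cand_marks <- lapply(seq_len(nrow(rows)), function(i) {
        mark_steady_state(fl, rows[i, ], settle_s, window_s)
      })
      cand_tbl <- dplyr::bind_rows(cand_marks)
      marks[[st]] <- cand_tbl[which.max(cand_tbl$mean_flux), , drop = FALSE]
    } else {
      # latest sub-segment (e.g. LEAK after glutamate, before ADP)
      marks[[st]] <- mark_steady_state(fl, rows[nrow(rows), ],
                                       settle_s, window_s)
    }
  }
  out <- dplyr::bind_rows(marks)

  rox <- out$mean_flux[out$state == "ROX"]
  if (length(rox) != 1) {
    abort("protocol produced no ROX (residual) state; cannot ROX-correct.")
  }
  out$raw_flux <- out$mean_flux
  out$rox_corrected_flux <- out$raw_flux - rox
  out$rox_corrected_flux[out$state == "ROX"] <- 0
  neg <- out$state[out$rox_corrected_flux < -1e-6 & out$state != "ROX"]
  if (length(neg) > 0) {
    warn(paste0("negative ROX-corrected flux in state(s) ",
                paste(neg, collapse = ", "), "; reported as-is."))
  }
  out <- tibble::tibble(
    sample_id = attr(run$trace, "sample_id"),
    group = run$group,
    state = out$state,
    raw_flux = out$raw_flux,
    rox_corrected_flux = out$rox_corrected_flux,
    t_start = out$t_start, t_end = out$t_end,
    sd_flux = out$sd_flux, n_points = out$n_points
  )
  structure(out, class = c("state_flux_tbl", class(out)))
}

#' Run the per-run pipeline over a list of runs
#'
#' @param runs A list of [run_record()] objects.
#' @param ... Passed to [state_fluxes()].
#' @return A `state_flux_tbl` tibble with one row per run and state.
#' @export
analyze_runs <- function(runs, ...) {
  stopifnot(length(runs) >= 1)
  out <- dplyr::bind_rows(lapply(runs, state_fluxes, ...))
  structure(out, class = unique(c("state_flux_tbl", class(out))))
}
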