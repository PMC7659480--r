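# Concentration -> volume-specific -> cell-specific oxygen flux.

new_flux_series <- function(time_s, j_total, j_sample = NA_real_,
                            j_cell = NA_real_) {
  out <- tibble::tibble(time_s = time_s, j_total = j_total,
                        j_sample = j_sample, j_cell = j_cell)
  structure(out, class = c("flux_series", class(out)))
}

# Sliding local linear-regression slope, one segment, O(n) via prefix sums.
# Window is [t_i - w/2, t_i + w/2] clipped to the segment (one-sided at the
# ends), so the smoothing never reaches across a segment boundary.
segment_slopes <- function(t, y, window_s) {
  n <- length(t)
  half <- window_s / 2
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  St <- c(0, cumsum(t)); Sy <- c(0, cumsum(y))
  Stt <- c(0, cumsum(t * t)); Sty <- c(0, cumsum(t * y))
  csum <- function(S, i, j) S[j + 1L] - S[i]
  m <- hi - lo + 1L
  if (any(m < 2L)) abort("derivative window spans fewer than 2 samples.")
  sx <- csum(St, lo, hi); sy <- csum(Sy, lo, hi)
  sxx <- csum(Stt, lo, hi); sxy <- csum(Sty, lo, hi)
  denom <- m * sxx - sx^2
  (m * sxy - sx * sy) / denom
}

#' Differentiate an oxygen trace into volume-specific flux
#'
#' Converts the concentration signal into total volume-specific oxygen flux
#' `j_total(t) = -dC/dt * 1000` (µM/s to pmol/(s·mL)); respiration (oxygen
#' removal) is positive. The derivative is a sliding local linear regression
#' (default) or a Savitzky-Golay filter. When event times are supplied the
#' smoothing window never crosses an event: the flux is estimated
#' independently on each inter-event segment, with one-sided windows at
#' segment ends.
#'
#' @param trace An [oxygen_trace()].
#' @param window_s Smoothing window length in seconds (must span >= 5
#'   samples).
#' @param method `"sliding-regression"` or `"savitzky-golay"`.
#' @param break_times Event times splitting the trace into independent
#'   segments (optional).
#' @return A `flux_series` tibble with `time_s` and `j_total` filled.
#' @export
#' @examples
#' tr <- oxygen_trace(seq(0, 100, 2), 100 - 0.1 * seq(0, 100, 2))
#' derive_flux(tr, window_s = 20)$j_total[1] # 100 pmol/(s*mL)
derive_flux <- function(trace, window_s = 20,
                        method = c("sliding-regression", "savitzky-golay"),
                        break_times = NULL) {
  stopifnot(inherits(trace, "oxygen_trace"))
  method <- match.arg(method)
  t <- trace$time_s; y <- trace$o2_um
  if (any(diff(t) <= 0)) abort("non-monotonic time in trace.")
  dt_med <- stats::median(diff(t))
  if (window_s / dt_med < 4) {
    abort("`window_s` must span at least 5 samples.")
  }

  breaks <- sort(unique(break_times))
  breaks <- breaks[breaks > t[1] & breaks < t[length(t)]]
  # segment index per sample: events belong to the segment they open
  seg_id <- findInterval(t, breaks)
  slope <- numeric(length(t))
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 5) {
      abort("an inter-event segment spans fewer than 5 samples.")
    }
    if (method == "sliding-regression") {
      slope[idx] <- segment_slopes(t[idx], y[idx], window_s)
    } else {
      np <- max(5L, round(window_s / dt_med) + 1L)
      if (np %% 2 == 0) np <- np + 1L
      np <- min(np, length(idx) - (1 - length(idx) %% 2))
      if (np < 5) abort("an inter-event segment spans fewer than 5 samples.")
      slope[idx] <- signal::sgolayfilt(y[idx], p = 2, n = np, m = 1,
                                       ts = dt_med)
    }
  }
  new_flux_series(t, j_total = -1000 * slope)
}

#' Subtract the instrumental background flux
#'
#' Removes the calibrated instrumental/chemical background,
#' `a + b * C(t)` pmol/(s·mL), from the total flux, filling `j_sample`.
#'
#' @param flux A `flux_series` from [derive_flux()].
#' @param trace The [oxygen_trace()] the flux was derived from (same grid).
#' @param chamber A [chamber_config()] carrying `background_a`,
#'   `background_b`.
#' @return The `flux_series` with `j_sample` filled.
#' @export
subtract_background <- function(flux, trace, chamber) {
  stopifnot(inherits(flux, "flux_series"), inherits(trace, "oxygen_trace"),
            inherits(chamber, "chamber_config"))
  if (nrow(flux) != nrow(trace) ||
      !isTRUE(all.equal(flux$time_s, trace$time_s, tolerance = 0))) {
    abort("flux and trace are not on the same time grid.")
  }
  flux$j_sample <- flux$j_total -
    (chamber$background_a + chamber$background_b * trace$o2_um)
  flux
}

#' Normalize flux per million cells
#'
#' `j_cell = j_sample * volume_mL / cell_count_millions`, in
#' pmol/(s·10^6 cells).
#'
#' @inheritParams subtract_background
#' @return The `flux_series` with `j_cell` filled.
#' @export
normalize_per_cells <- function(flux, chamber) {
  stopifnot(inherits(flux, "flux_series"), inherits(chamber, "chamber_config"))
  if (all(is.na(flux$j_sample))) abort("`j_sample` not filled yet.")
  if (chamber$cell_mio <= 0) abort("`cell_mio` must be > 0.")
  flux$j_cell <- flux$j_sample * chamber$volume_ml / chamber$cell_mio
  flux
}
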