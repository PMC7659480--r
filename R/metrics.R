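# Derived ratios: flux control ratios, coupling, reserve, CII factors.

corrected <- function(table, state, required = TRUE) {
  v <- table$rox_corrected_flux[table$state == state]
  if (length(v) == 0) {
    if (required) abort(paste0("state ", state, " absent from table."))
    return(NA_real_)
  }
  if (length(v) > 1) abort(paste0("state ", state, " not unique; pass a single run."))
  v
}

ref_flux <- function(table, reference = "ETS") {
  e <- corrected(table, reference)
  if (e == 0) abort("degenerate reference: ROX-corrected reference flux is 0.")
  e
}

#' Flux control ratio
#'
#' A state's ROX-corrected flux divided by the ROX-corrected flux of the
#' reference state (the maximal uncoupled ETS capacity by default). FCRs are
#' independent of mitochondrial content and cell number.
#'
#' @param table A single-run `state_flux_tbl` (see [state_fluxes()]).
#' @param state State label.
#' @param reference Reference state (default `"ETS"`).
#' @return A dimensionless ratio; `fcr(table, reference)` is exactly 1.
#' @export
fcr <- function(table, state, reference = "ETS") {
  corrected(table, state) / ref_flux(table, reference)
}

#' Net (ATP-coupled) flux control ratio
#'
#' Each state corrected for the dissipative LEAK respiration, expressed as an
#' FCR: `(J_state - J_LEAK) / J_ref` on ROX-corrected fluxes. Equals
#' `fcr(state) - fcr(LEAK)`.
#'
#' @inheritParams fcr
#' @export
net_fcr <- function(table, state, reference = "ETS") {
  (corrected(table, state) - corrected(table, "LEAK")) /
    ref_flux(table, reference)
}

#' Coupling efficiency of a respiratory state
#'
#' The fraction of a state's (ROX-corrected) oxygen flux coupled to ADP
#' phosphorylation: `1 - J_LEAK / J_state`. Stored as a fraction; rendered as
#' a percentage in reports.
#'
#' @inheritParams fcr
#' @export
coupling_efficiency <- function(table, state) {
  js <- corrected(table, state)
  if (js == 0) abort("state flux is 0: coupling efficiency undefined.")
  1 - corrected(table, "LEAK") / js
}

#' Respiratory reserve
#'
#' Spare phosphorylating capacity above the cell's ROUTINE demand, expressed
#' in FCR units. By definition here `(J_OXPHOS - J_ROUTINE) / J_ETS`
#' (`definition = "oxphos"`); the alternative convention
#' `(J_ETS - J_ROUTINE) / J_ETS` is available as `definition = "ets"`.
#' Both are independent of LEAK.
#'
#' @inheritParams fcr
#' @param definition `"oxphos"` (default) or `"ets"`.
#' @export
respiratory_reserve <- function(table, definition = c("oxphos", "ets"),
                                reference = "ETS") {
  definition <- match.arg(definition)
  top <- if (definition == "oxphos") corrected(table, "OXPHOS")
         else corrected(table, "ETS")
  (top - corrected(table, "ROUTINE")) / ref_flux(table, reference)
}

#' FCR of ETS capacity sustained by complex II
#'
#' Complex II-driven ETS (after rotenone inhibition of complex I) relative to
#' the convergent CI+CII ETS capacity: `J_ETS_CII / J_ETS` on ROX-corrected
#' fluxes.
#'
#' @inheritParams fcr
#' @export
cii_ets_fcr <- function(table, reference = "ETS") {
  corrected(table, "ETS_CII") / ref_flux(table, reference)
}

#' Substrate control factor for complex II
#'
#' The oxygen flux linked to complex II (OXPHOS_CII of a rotenone-first run,
#' corrected for its post-malonate residual baseline, which plays the ROX
#' role in that protocol) normalized to the convergent complex I + complex II
#' OXPHOS flux of the paired no-rotenone reference run. Runs are paired by
#' `sample_id`.
#'
#' @param cii_table `state_flux_tbl` of one SUIT_CII run (has OXPHOS_CII).
#' @param reference_table `state_flux_tbl` of the paired reference run (has
#'   OXPHOS).
#' @return A dimensionless ratio, expected in `[0, 1]`; values outside are
#'   returned with a warning.
#' @export
scf_cii <- function(cii_table, reference_table) {
  id_c <- unique(cii_table$sample_id)
  id_r <- unique(reference_table$sample_id)
  if (length(id_c) != 1 || length(id_r) != 1 || !identical(id_c, id_r)) {
    abort("unpaired runs: SCF needs one CII run and one reference run sharing a sample_id.")
  }
  num <- corrected(cii_table, "OXPHOS_CII")
  den <- corrected(reference_table, "OXPHOS")
  if (den == 0) abort("reference OXPHOS flux is 0: SCF undefined.")
  out <- num / den
  if (num >= 0 && den > 0 && (out < 0 || out > 1)) {
    warn(paste0("SCF outside [0, 1]: ", format(out)))
  }
  out
}

#' Percent change between group values
#'
#' The signed contrast statistic used throughout group comparisons:
#' `(treated - control) / control * 100`.
#'
#' @param control_value,treated_value Numbers; `control_value` must be
#'   nonzero.
#' @return Signed percent (e.g. `+63` for 0.19 to 0.31).
#' @export
#' @examples
#' percent_change(0.19, 0.31) # +63.2
percent_change <- function(control_value, treated_value) {
  if (any(control_value == 0)) abort("control value is 0: percent change undefined.")
  (treated_value - control_value) / control_value * 100
}

# states whose coupling efficiency is reported (those with a phosphorylating
# or uncoupled component above LEAK)
coupling_states <- function(states) {
  intersect(c("ROUTINE", "OXPHOS_CI", "OXPHOS", "ETS"), states)
}

#' Compute the full per-run metrics table
#'
#' Derives, for every run in a `state_flux_tbl`, the FCR and net FCR of each
#' non-ROX state, the coupling efficiencies of ROUTINE/OXPHOS_CI/OXPHOS/ETS,
#' the respiratory reserve, and (when ETS_CII is present) the complex
#' II-linked ETS FCR.
#'
#' @param table A `state_flux_tbl`, possibly holding several runs.
#' @param rr_definition Respiratory-reserve convention, see
#'   [respiratory_reserve()].
#' @return A long tibble: `sample_id`, `group`, `metric`, `state`, `value`.
#' @export
compute_metrics <- function(table, rr_definition = c("oxphos", "ets")) {
  rr_definition <- match.arg(rr_definition)
  runs <- split(table, table$sample_id)
  rows <- lapply(runs, function(tb) {
    sts <- setdiff(tb$state, c("ROX", "NULL"))
    out <- list()
    if ("ETS" %in% tb$state) {
      out$fcr <- tibble::tibble(metric = "fcr", state = sts,
                                value = unname(vapply(sts, fcr, 0, table = tb)))
      if ("LEAK" %in% tb$state) {
        out$net <- tibble::tibble(metric = "net_fcr", state = sts,
                                  value = unname(vapply(sts, net_fcr, 0, table = tb)))
      }
      if ("ETS_CII" %in% tb$state) {
        out$cii <- tibble::tibble(metric = "cii_ets_fcr", state = "ETS_CII",
                                  value = cii_ets_fcr(tb))
      }
      if (all(c("ROUTINE", "OXPHOS") %in% tb$state)) {
        out$rr <- tibble::tibble(
          metric = "respiratory_reserve", state = NA_character_,
          value = respiratory_reserve(tb, rr_definition)
        )
      }
    }
    cs <- coupling_states(tb$state)
    if ("LEAK" %in% tb$state && length(cs) > 0) {
      out$coupling <- tibble::tibble(
        metric = "coupling_efficiency", state = cs,
        value = unname(vapply(cs, coupling_efficiency, 0, table = tb))
      )
    }
    res <- dplyr::bind_rows(out)
    res$sample_id <- tb$sample_id[1]
    res$group <- tb$group[1]
    res
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("sample_id", "group", "metric", "state", "value")]
  structure(out, class = c("metrics_tbl", class(out)))
}
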