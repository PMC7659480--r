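# Domain types: oxygen trace, titration events, chamber, protocol, run record.

#' Construct an oxygen trace
#'
#' A sampled chamber oxygen-concentration time series. Time is in seconds on a
#' trace-local clock starting at acquisition; concentration is in µM
#' (= nmol/mL), assumed pre-calibrated.
#'
#' Slightly negative concentrations (noise around an anoxic chamber) are kept
#' and flagged with a warning; values below -5 µM are rejected.
#'
#' @param time_s Numeric vector, strictly increasing, >= 0.
#' @param o2_um Oxygen concentration in µM, same length as `time_s`.
#' @param chamber_id,sample_id Opaque labels.
#' @param temperature Assay temperature in °C (metadata only).
#' @return A tibble of class `oxygen_trace` with columns `time_s`, `o2_um`.
#' @export
#' @examples
#' oxygen_trace(0:10, 180 - 0.1 * (0:10))
oxygen_trace <- function(time_s, o2_um, chamber_id = "A", sample_id = "S1",
                         temperature = 37) {
  if (length(time_s) != length(o2_um)) {
    abort("`time_s` and `o2_um` must have the same length.")
  }
  if (length(time_s) < 2) abort("an oxygen trace needs at least 2 samples.")
  if (anyNA(time_s) || any(!is.finite(time_s)) || any(time_s < 0)) {
    abort("`time_s` must be finite and >= 0.")
  }
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (anyNA(o2_um) || any(!is.finite(o2_um))) abort("`o2_um` must be finite.")
  if (any(o2_um < -5)) {
    abort("`o2_um` below -5 µM: not a calibrated oxygen signal.")
  }
  if (any(o2_um < 0)) {
    warn("trace contains negative o2_um values (> -5 µM); kept and flagged.")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), o2_um = as.numeric(o2_um))
  structure(out,
    class = c("oxygen_trace", class(out)),
    chamber_id = chamber_id, sample_id = sample_id,
    temperature = temperature, negative_o2 = any(o2_um < 0)
  )
}

#' Construct a titration-event log
#'
#' Timestamped reagent additions driving the protocol's state transitions.
#' Events must be sorted in time; every reagent except CCCP (which is titrated
#' stepwise) may appear at most once per run.
#'
#' @param time_s Event times, seconds, same clock as the trace.
#' @param reagent Labels from [hrr_reagents()].
#' @param dose,units Optional dose metadata (never used in computation).
#' @return A tibble of class `titration_events`.
#' @export
titration_events <- function(time_s, reagent, dose = NA_real_,
                             units = NA_character_) {
  reagent <- as.character(reagent)
  bad <- setdiff(unique(reagent), hrr_reagents())
  if (length(bad) > 0) {
    abort(paste0("unknown reagent label(s): ", paste(bad, collapse = ", "),
                 ". Valid labels: ", paste(hrr_reagents(), collapse = ", ")))
  }
  if (is.unsorted(time_s, strictly = FALSE)) {
    abort("events must be sorted by time.")
  }
  dup <- reagent[duplicated(reagent)]
  if (any(dup != "CCCP")) {
    abort(paste0("reagent(s) repeated but only CCCP may repeat: ",
                 paste(unique(dup[dup != "CCCP"]), collapse = ", ")))
  }
  out <- tibble::tibble(
    time_s = as.numeric(time_s), reagent = reagent,
    dose = rep_len(as.numeric(dose), length(time_s)),
    units = rep_len(as.character(units), length(time_s))
  )
  structure(out, class = c("titration_events", class(out)))
}

#' Chamber configuration
#'
#' Physical and calibration parameters of one oxygraph chamber. The
#' instrumental/chemical background flux is modelled as linear in oxygen
#' concentration, `a + b * C`, with parameters assumed pre-calibrated.
#'
#' @param volume_ml Chamber volume in mL (> 0).
#' @param cell_mio Cell count in millions (> 0).
#' @param stir_rpm Stirrer speed (metadata).
#' @param background_a Background flux offset, pmol/(s·mL).
#' @param background_b Background flux slope per µM O2, pmol/(s·mL·µM).
#' @return A list of class `chamber_config`.
#' @export
chamber_config <- function(volume_ml = 2.0, cell_mio, stir_rpm = 750,
                           background_a = 0, background_b = 0) {
  if (!is.numeric(volume_ml) || volume_ml <= 0) abort("`volume_ml` must be > 0.")
  if (missing(cell_mio) || !is.numeric(cell_mio) || cell_mio <= 0) {
    abort("`cell_mio` (millions of cells) must be > 0.")
  }
  structure(
    list(volume_ml = volume_ml, cell_mio = cell_mio, stir_rpm = stir_rpm,
         background_a = background_a, background_b = background_b),
    class = "chamber_config"
  )
}

#' Define a SUIT protocol
#'
#' A protocol maps the ordered reagent additions of a
#' substrate-uncoupler-inhibitor titration to the respiratory states they
#' open. Consecutive transitions may enter the same state (e.g. glutamate
#' keeps LEAK open until ADP). The first acquisition segment, before any
#' event, is always ROUTINE.
#'
#' @param name Protocol label.
#' @param transitions Data frame with columns `reagent`, `state`: trigger
#'   reagent and the state entered, in titration order.
#' @param reference_state State used as the flux-control-ratio denominator.
#' @param ets_rule How the ETS plateau is located across uncoupler titration
#'   steps; only `"max_plateau"` is defined (maximum mean flux over steps).
#' @param doses Optional named list of dose metadata per reagent.
#' @return A list of class `protocol_definition`.
#' @seealso [builtin_protocol()] for the two built-in protocols.
#' @export
protocol_definition <- function(name, transitions, reference_state = "ETS",
                                ets_rule = "max_plateau", doses = list()) {
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("reagent", "state") %in% names(transitions)))
  bad_r <- setdiff(transitions$reagent, hrr_reagents())
  if (length(bad_r)) abort(paste0("unknown trigger reagent(s): ",
                                  paste(bad_r, collapse = ", ")))
  bad_s <- setdiff(transitions$state, hrr_states())
  if (length(bad_s)) abort(paste0("unknown state label(s): ",
                                  paste(bad_s, collapse = ", ")))
  if (length(reference_state) != 1 || !reference_state %in% hrr_states()) {
    abort("exactly one valid `reference_state` is required.")
  }
  if (!identical(ets_rule, "max_plateau")) {
    abort("only ets_rule = \"max_plateau\" is defined.")
  }
  dup <- transitions$reagent[duplicated(transitions$reagent)]
  if (length(dup)) abort("a reagent may trigger at most one transition.")
  structure(
    list(name = name, transitions = transitions,
         reference_state = reference_state, ets_rule = ets_rule,
         doses = doses),
    class = "protocol_definition"
  )
}

#' Built-in SUIT protocols
#'
#' `SUIT_MAIN` is the full titration walking intact cells through ROUTINE,
#' then (after digitonin permeabilization with pyruvate/malate present) LEAK,
#' complex I-driven OXPHOS (ADP), convergent CI+CII OXPHOS (succinate),
#' uncoupled ETS capacity (stepwise CCCP), complex II-driven ETS (rotenone)
#' and residual oxygen consumption ROX (antimycin). `SUIT_CII` inhibits
#' complex I with rotenone immediately after permeabilization (so ADP opens no
#' phosphorylating state), measures complex II-driven OXPHOS on succinate, and
#' uses malonate to return the signal to its residual baseline, which plays
#' the ROX role; its flux-control reference is the OXPHOS state of a paired
#' no-rotenone run.
#'
#' Substrate doses are attached as metadata only.
#'
#' @param name `"SUIT_MAIN"` or `"SUIT_CII"`.
#' @return A [protocol_definition()].
#' @export
#' @examples
#' builtin_protocol("SUIT_MAIN")$reference_state
builtin_protocol <- function(name) {
  doses <- list(
    PM = "5 mM pyruvate + 2 mM malate", DIG = "4.07 uM digitonin",
    G = "10 mM glutamate", ADP = "2.5 mM ADP", S = "10 mM succinate",
    CCCP = "0.5 uM CCCP per step", ROT = "2 uM rotenone",
    AMA = "2.5 uM antimycin A", MAL = "5 mM malonic acid"
  )
  switch(name,
    SUIT_MAIN = protocol_definition(
      name = "SUIT_MAIN",
      transitions = tibble::tibble(
        reagent = c("DIG", "G", "ADP", "S", "CCCP", "ROT", "AMA"),
        state = c("LEAK", "LEAK", "OXPHOS_CI", "OXPHOS", "ETS", "ETS_CII",
                  "ROX")
      ),
      reference_state = "ETS",
      doses = doses[c("PM", "DIG", "G", "ADP", "S", "CCCP", "ROT", "AMA")]
    ),
    SUIT_CII = protocol_definition(
      name = "SUIT_CII",
      transitions = tibble::tibble(
        reagent = c("DIG", "ROT", "ADP", "S", "MAL"),
        state = c("LEAK", "NULL", "NULL", "OXPHOS_CII", "ROX")
      ),
      reference_state = "OXPHOS",
      doses = doses[c("PM", "DIG", "ROT", "ADP", "S", "MAL")]
    ),
    abort(paste0("unknown protocol \"", name,
                 "\"; valid protocols: SUIT_MAIN, SUIT_CII."))
  )
}

#' Bundle one chamber run
#'
#' @param trace An [oxygen_trace()].
#' @param events A [titration_events()] log.
#' @param chamber A [chamber_config()].
#' @param protocol A [protocol_definition()].
#' @param group Group label, e.g. `"control"` or `"MPP+"`.
#' @return A list of class `run_record`.
#' @export
run_record <- function(trace, events, chamber, protocol, group = "control") {
  stopifnot(inherits(trace, "oxygen_trace"),
            inherits(events, "titration_events"),
            inherits(chamber, "chamber_config"),
            inherits(protocol, "protocol_definition"))
  structure(
    list(trace = trace, events = events, chamber = chamber,
         protocol = protocol, group = as.character(group)),
    class = "run_record"
  )
}

new_diagnostic <- function(severity, message) {
  tibble::tibble(severity = severity, message = message)
}

empty_diagnostics <- function() {
  tibble::tibble(severity = character(), message = character())
}

#' Validate a run against its protocol
#'
#' Checks the run's structural invariants and that the event log satisfies
#' the protocol's transition order. Problems are returned as a diagnostics
#' table (severity `"error"` or `"warning"`), never thrown.
#'
#' @param run A [run_record()].
#' @return A tibble with columns `severity`, `message`; zero rows when the
#'   run fully conforms.
#' @export
validate_run <- function(run) {
  stopifnot(inherits(run, "run_record"))
  diags <- empty_diagnostics()
  add <- function(severity, message) {
    diags <<- dplyr::bind_rows(diags, new_diagnostic(severity, message))
  }

  tr <- run$trace
  ev <- run$events
  span <- range(tr$time_s)
  if (isTRUE(attr(tr, "negative_o2"))) {
    add("warning", "trace contains negative oxygen concentrations (noise).")
  }
  if (nrow(ev) > 0 && (any(ev$time_s < span[1]) || any(ev$time_s > span[2]))) {
    add("error", "event time(s) outside the trace time span.")
  }

  # Protocol satisfiability: required reagents present, in transition order;
  # CCCP may repeat (consecutively in protocol position).
  proto <- run$protocol
  req <- proto$transitions$reagent
  obs <- ev$reagent[ev$reagent %in% req]
  pos <- match(obs, req)
  if (length(pos) > 1 && any(diff(pos) < 0)) {
    add("error", paste0("event order violates protocol ", proto$name, "."))
  }
  missing_r <- setdiff(req, obs)
  if (length(missing_r) > 0) {
    st <- proto$transitions$state[match(missing_r, proto$transitions$reagent)]
    add("error", paste0(
      "no ", paste(unique(st), collapse = "/"),
      " state reachable: missing event(s) ",
      paste(missing_r, collapse = ", "), "."
    ))
  }
  extra <- setdiff(unique(ev$reagent), c(req, "PM"))
  if (length(extra) > 0) {
    add("warning", paste0("event(s) not used by protocol ", proto$name, ": ",
                          paste(extra, collapse = ", "), "."))
  }
  diags
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record> protocol:", x$protocol$name, " group:", x$group, "\n")
  cat("  trace:", nrow(x$trace), "samples over",
      round(diff(range(x$trace$time_s))), "s;",
      nrow(x$events), "events\n")
  cat("  chamber:", x$chamber$volume_ml, "mL,", x$chamber$cell_mio,
      "x10^6 cells\n")
  invisible(x)
}

#' @export
print.protocol_definition <- function(x, ...) {
  cat("<protocol_definition>", x$name, "- reference state:",
      x$reference_state, "\n")
  print(x$transitions, n = Inf)
  invisible(x)
}
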