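# Group-level summaries and control-vs-treated comparisons.

#' Summarize a vector of per-run values
#'
#' @param values Numeric vector, length >= 1.
#' @return A list with `mean`, `sd` (sample sd, n-1 denominator; `NA` for a
#'   single value) and `n`.
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no values to summarize.")
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare two groups with an unpaired t-test
#'
#' Two-sided unpaired t-test (Student's equal-variance by default; Welch
#' behind `variant = "welch"`), plus the percent change of group means and
#' significance stars at the 0.05 / 0.01 / 0.001 thresholds. No
#' multiple-testing correction is applied: each contrast carries its own p.
#'
#' @param control,treated Numeric vectors of per-run values, n >= 2 each.
#' @param variant `"student"` or `"welch"`.
#' @param metric,state Optional labels carried into the output row.
#' @return A one-row tibble: `metric`, `state`, `mean_control`, `sd_control`,
#'   `n_control`, `mean_treated`, `sd_treated`, `n_treated`,
#'   `percent_change`, `t_statistic`, `p_value`, `stars`.
#' @export
compare_groups <- function(control, treated,
                           variant = c("student", "welch"),
                           metric = NA_character_, state = NA_character_) {
  variant <- match.arg(variant)
  control <- control[!is.na(control)]
  treated <- treated[!is.na(treated)]
  if (length(control) < 2 || length(treated) < 2) {
    abort("need at least 2 values per group for a t-test.")
  }
  sc <- summarize_values(control)
  st <- summarize_values(treated)
  if (sc$sd == 0 && st$sd == 0) {
    # degenerate but well-defined: constant groups (e.g. the reference-state
    # FCR, identically 1 in every run)
    tt <- if (sc$mean == st$mean) list(statistic = 0, p.value = 1)
          else list(statistic = sign(st$mean - sc$mean) * Inf, p.value = 0)
  } else {
    tt <- stats::t.test(treated, control, var.equal = (variant == "student"))
  }
  p <- unname(tt$p.value)
  tibble::tibble(
    metric = metric, state = state,
    mean_control = sc$mean, sd_control = sc$sd, n_control = sc$n,
    mean_treated = st$mean, sd_treated = st$sd, n_treated = st$n,
    percent_change = if (sc$mean != 0) percent_change(sc$mean, st$mean)
                     else NA_real_, # undefined against a zero baseline
    t_statistic = unname(tt$statistic),
    p_value = p,
    stars = significance_stars(p)
  )
}

#' Full control-vs-treated contrast panel
#'
#' Builds the complete comparison report of the two-group analysis: per-state
#' ROX-corrected flux, FCR, net FCR, coupling efficiency, respiratory
#' reserve, complex II-linked ETS FCR and, when paired rotenone-first runs
#' are supplied, the complex II substrate control factor. Runs missing the
#' LEAK state are excluded from LEAK-dependent rows with a warning (their n
#' is decremented).
#'
#' @param control_fluxes,treated_fluxes `state_flux_tbl` tables (several runs
#'   each) from the main protocol.
#' @param cii_control,cii_treated Optional `state_flux_tbl` tables from the
#'   rotenone-first (SUIT_CII) protocol, paired to the main runs by
#'   `sample_id`.
#' @param variant t-test variant, see [compare_groups()].
#' @param rr_definition Respiratory-reserve convention.
#' @return A tibble of class `comparison_tbl`, one row per metric x state.
#' @export
compare_cohorts <- function(control_fluxes, treated_fluxes,
                            cii_control = NULL, cii_treated = NULL,
                            variant = c("student", "welch"),
                            rr_definition = c("oxphos", "ets")) {
  variant <- match.arg(variant)
  rr_definition <- match.arg(rr_definition)

  drop_leakless <- function(tb) {
    keep <- vapply(split(tb, tb$sample_id),
                   function(x) "LEAK" %in% x$state, TRUE)
    if (!all(keep)) {
      warn(paste0("run(s) without a LEAK state excluded: ",
                  paste(names(keep)[!keep], collapse = ", ")))
      tb <- tb[tb$sample_id %in% names(keep)[keep], , drop = FALSE]
    }
    tb
  }
  control_fluxes <- drop_leakless(control_fluxes)
  treated_fluxes <- drop_leakless(treated_fluxes)

  rows <- list()

  # per-state ROX-corrected fluxes
  flux_states <- intersect(
    c("ROUTINE", "LEAK", "OXPHOS_CI", "OXPHOS", "ETS", "ETS_CII"),
    intersect(control_fluxes$state, treated_fluxes$state)
  )
  for (st in flux_states) {
    rows[[paste0("flux.", st)]] <- compare_groups(
      control_fluxes$rox_corrected_flux[control_fluxes$state == st],
      treated_fluxes$rox_corrected_flux[treated_fluxes$state == st],
      variant, metric = "flux", state = st
    )
  }

  mc <- compute_metrics(control_fluxes, rr_definition)
  mt <- compute_metrics(treated_fluxes, rr_definition)
  keys <- dplyr::inner_join(
    dplyr::distinct(mc[, c("metric", "state")]),
    dplyr::distinct(mt[, c("metric", "state")]),
    by = c("metric", "state")
  )
  for (i in seq_len(nrow(keys))) {
    m <- keys$metric[i]; s <- keys$state[i]
    pick <- function(tb) {
      tb$value[tb$metric == m & (tb$state == s | (is.na(s) & is.na(tb$state)))]
    }
    rows[[paste(m, s, sep = ".")]] <-
      compare_groups(pick(mc), pick(mt), variant, metric = m, state = s)
  }

  if (!is.null(cii_control) && !is.null(cii_treated)) {
    scf_values <- function(cii_tb, ref_tb) {
      ids <- intersect(unique(cii_tb$sample_id), unique(ref_tb$sample_id))
      vapply(ids, function(id) {
        scf_cii(cii_tb[cii_tb$sample_id == id, ],
                ref_tb[ref_tb$sample_id == id, ])
      }, 0)
    }
    rows[["scf.OXPHOS_CII"]] <- compare_groups(
      scf_values(cii_control, control_fluxes),
      scf_values(cii_treated, treated_fluxes),
      variant, metric = "scf", state = "OXPHOS_CII"
    )
  }

  out <- dplyr::bind_rows(rows)
  structure(out, class = c("comparison_tbl", class(out)))
}

#' Render a comparison panel as a text table
#'
#' @param comparison A `comparison_tbl` from [compare_cohorts()].
#' @return The input, invisibly; the table is printed. Coupling efficiencies
#'   are rendered as percentages.
#' @export
format_comparison <- function(comparison) {
  df <- as.data.frame(comparison)
  pct <- df$metric == "coupling_efficiency"
  for (col in c("mean_control", "sd_control", "mean_treated", "sd_treated")) {
    df[[col]] <- ifelse(pct, 100 * df[[col]], df[[col]])
  }
  df$label <- ifelse(pct, paste0(df$metric, " (%)"), df$metric)
  lines <- sprintf(
    "%-28s %-10s %8.3f ± %6.3f (n=%d) vs %8.3f ± %6.3f (n=%d)  %+7.1f%%  p=%.4g %s",
    df$label, ifelse(is.na(df$state), "", df$state),
    df$mean_control, df$sd_control, df$n_control,
    df$mean_treated, df$sd_treated, df$n_treated,
    df$percent_change, df$p_value, df$stars
  )
  cat(lines, sep = "\n")
  invisible(comparison)
}
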