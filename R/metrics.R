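#' Average percent reduction in free TNF-alpha from pathological levels
#'
#' `(1 - C_avg / (SF * C_healthy)) * 100`, reported with the positive
#' magnitude convention (a fully suppressed target gives 100, untreated
#' disease gives 0).
#'
#' @param C_avg Average free TNF-alpha concentration at steady state, pM.
#' @param SF Synthesis factor.
#' @param C_healthy Healthy baseline concentration, pM.
#' @return Percent reduction.
#' @examples
#' red_percent(0.7, 7, 1)  # 90, the therapeutic objective
#' @export
red_percent <- function(C_avg, SF, C_healthy) {
  if (any(SF * C_healthy <= 0)) stop("SF * C_healthy must be positive")
  if (any(C_avg < 0)) stop("C_avg must be >= 0")
  (1 - C_avg / (SF * C_healthy)) * 100
}

#' Steady-state exposure fold change between routes
#'
#' Ratio of the intravitreal steady-state drug concentration to the average
#' intravenous steady-state concentration, rounded to 2 decimals for
#' reporting.
#'
#' @param C_ss_ivt,C_avg_ss_iv Concentrations, pM.
#' @return Dimensionless fold change.
#' @export
fold_change <- function(C_ss_ivt, C_avg_ss_iv) {
  if (any(C_avg_ss_iv <= 0)) stop("denominator must be positive")
  round(C_ss_ivt / C_avg_ss_iv, 2)
}

#' Percent reduction in total annual dose of the intravitreal regimen
#'
#' @param iv_total,ivt_total Total annual doses, ug.
#' @return `(1 - ivt_total / iv_total) * 100`, 1-decimal rounding.
#' @export
dose_reduction_percent <- function(iv_total, ivt_total) {
  if (any(iv_total <= 0)) stop("iv_total must be positive")
  round((1 - ivt_total / iv_total) * 100, 1)
}

#' Free TNF-alpha over free drug concentration ratio
#'
#' Pointwise ratio of the two series at one location; emitted as `NA` where
#' the free drug concentration is below `floor_pM` (guarded division).
#'
#' @param sim A `tnf_sim`.
#' @param location Compartment with both species.
#' @param floor_pM Free-drug floor below which the ratio is undefined.
#' @return data.frame with `time_h` and `ratio`.
#' @export
free_ratio_series <- function(sim, location, floor_pM = 1e-6) {
  tnf <- sim_series(sim, location, "tnf_free")
  drg <- sim_series(sim, location, "drug")
  ratio <- ifelse(drg < floor_pM, NA_real_, tnf / drg)
  data.frame(time_h = sim$time_h, ratio = ratio)
}

OUTCOME_LEVELS <- c("all_below_objective", "first_above_objective",
                    "all_above_baseline", "all_pathological")

#' Classify the TNF-alpha outcome at the next administration
#'
#' Given the free TNF-alpha concentration in all four modelled locations at
#' the time of the next device administration, assigns the device-failure
#' endpoint category (ordered by severity): every level below the therapeutic
#' objective; at least one level at or above the objective (carrying the
#' highest-concentration location); every level at or above baseline; every
#' level at the pathological concentration (within a tolerance band, since the
#' approach to the pathological plateau is asymptotic).
#'
#' @param concentrations Named numeric vector of free TNF-alpha (pM) for
#'   `venous_plasma`, `ICB_plasma`, `ICB_interstitial`, `AH`.
#' @param objective,baseline,pathological Thresholds, pM (defaults 0.7, 1, 7).
#' @param pathological_tol Fractional tolerance band on the pathological
#'   threshold (default 0.01).
#' @return An `outcome_classification`: list with ordered-factor `category`,
#'   `triggering_location` (or `NA`) and the input concentrations.
#' @export
classify_outcome <- function(concentrations, objective = 0.7, baseline = 1,
                             pathological = 7, pathological_tol = 0.01) {
  if (!all(TNF_COMPARTMENTS %in% names(concentrations)))
    stop("concentrations must name all of: ",
         paste(TNF_COMPARTMENTS, collapse = ", "))
  x <- concentrations[TNF_COMPARTMENTS]
  if (any(!is.finite(x))) stop("concentrations must be finite")
  category <- if (all(x >= pathological * (1 - pathological_tol))) {
    "all_pathological"
  } else if (all(x >= baseline)) {
    "all_above_baseline"
  } else if (any(x >= objective)) {
    "first_above_objective"
  } else {
    "all_below_objective"
  }
  loc <- NA_character_
  if (category == "first_above_objective") {
    # ties broken by fixed anatomical order, AH sentinel first
    order_pref <- c("AH", "ICB_interstitial", "ICB_plasma", "venous_plasma")
    xx <- x[order_pref]
    loc <- order_pref[which.max(xx)]
  }
  structure(list(category = factor(category, levels = OUTCOME_LEVELS,
                                   ordered = TRUE),
                 triggering_location = loc, concentrations = x),
            class = "outcome_classification")
}

#' @export
print.outcome_classification <- function(x, ...) {
  cat(sprintf("<outcome_classification> %s%s\n", as.character(x$category),
              if (!is.na(x$triggering_location))
                paste0(" (", x$triggering_location, ")") else ""))
  cat("  ", paste(sprintf("%s=%.3g pM", names(x$concentrations),
                          x$concentrations), collapse = "  "), "\n")
  invisible(x)
}

#' One-row regimen summary (dose, Red% by location)
#'
#' @param sim A `tnf_sim` of the regimen.
#' @param window_wk Steady-state window (NULL = default).
#' @return One-row data.frame: drug, route, n_administrations, total dose and
#'   Red% in the four TNF-alpha locations.
#' @export
regimen_summary <- function(sim, window_wk = NULL) {
  sch <- sim$schedule
  route <- if (any(sch$kind == "ivt_device_start")) "IVT" else "IV"
  reds <- vapply(TNF_COMPARTMENTS, function(loc)
    red_percent(steady_state_average(sim, loc, "tnf_free", window_wk),
                sim$target$SF, sim$target$baseline_conc), numeric(1))
  out <- data.frame(drug = sim$drug$name, route = route,
                    n_adm = nrow(sch),
                    total_dose_ug = round(total_annual_dose(sch), 1))
  for (loc in TNF_COMPARTMENTS)
    out[[paste0("red_pct_", loc)]] <- round(reds[[loc]], 1)
  out
}
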