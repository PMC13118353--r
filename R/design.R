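#' Design criterion for regimen optimization
#'
#' @param target_reduction Required average percent reduction in free
#'   TNF-alpha (default 90).
#' @param locations Locations that must all meet the target (default aqueous
#'   humour and the ICB interstitial biophase).
#' @param horizon Simulation horizon, weeks.
#' @return An object of class `design_criterion`.
#' @export
design_criterion <- function(target_reduction = 90,
                             locations = c("AH", "ICB_interstitial"),
                             horizon = 52) {
  if (target_reduction < 0 || target_reduction >= 100)
    stop("target_reduction must lie in [0, 100)")
  if (!all(locations %in% TNF_COMPARTMENTS))
    stop("locations must be TNF-alpha-bearing compartments")
  structure(list(target_reduction = target_reduction, locations = locations,
                 horizon = horizon), class = "design_criterion")
}

min_red_percent <- function(sim, criterion, window_wk = NULL) {
  min(vapply(criterion$locations, function(loc)
    red_percent(steady_state_average(sim, loc, "tnf_free", window_wk),
                sim$target$SF, sim$target$baseline_conc), numeric(1)))
}

# monotone bisection for the smallest x with f(x) >= target; f is the minimum
# Red% over the criterion locations, monotone increasing in dose/rate
bisect_design <- function(f, bracket, target, tol_rel = 1e-3,
                          max_iter = 12L) {
  lo <- bracket[1]; hi <- bracket[2]
  if (lo < 0 || hi <= lo) stop("bracket must satisfy 0 <= lo < hi")
  if (target <= 0) return(lo)
  f_lo <- f(lo)
  if (f_lo >= target) return(lo)
  f_hi <- f(hi)
  if (f_hi < target)
    stop("target unreachable in bracket [", lo, ", ", hi, "]: max Red% ",
         signif(f_hi, 4))
  for (i in seq_len(max_iter)) {
    if ((hi - lo) <= tol_rel * hi) break
    mid <- (lo + hi) / 2
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Reference intravenous dose meeting the reduction objective
#'
#' Bisection on the maintenance dose of the standard-of-care regimen
#' (loading double dose at week 1, maintenance every other week from week 2)
#' until the minimum steady-state Red% over the criterion locations meets the
#' target. The response is monotone in dose, so bisection returns the
#' smallest satisfying dose to within the tolerance.
#'
#' @param physiology,drug,target Model inputs.
#' @param criterion A [design_criterion()].
#' @param bracket Dose bracket, ug; Red% must straddle the target.
#' @param tol_rel Relative bracket tolerance.
#' @param ... Passed to [simulate_regimen()].
#' @return Reference dose, ug.
#' @export
find_reference_iv_dose <- function(physiology, drug, target,
                                   criterion = design_criterion(),
                                   bracket = c(1, 200), tol_rel = 1e-3, ...) {
  f <- function(dose) {
    sch <- build_iv_soc_schedule(iv_regimen(dose, horizon = criterion$horizon))
    min_red_percent(simulate_regimen(physiology, drug, target, sch,
                                     horizon_wk = criterion$horizon, ...),
                    criterion)
  }
  bisect_design(f, bracket, criterion$target_reduction, tol_rel)
}

#' Optimal zero-order intravitreal release rate
#'
#' Bisection on the device release rate (injections every 24 weeks) until the
#' minimum steady-state Red% over the criterion locations meets the target.
#'
#' @param physiology,drug,target Model inputs.
#' @param criterion A [design_criterion()].
#' @param bracket Rate bracket, ug/week.
#' @param tol_rel Relative bracket tolerance.
#' @param duration_wk,injection_times_wk Device geometry (defaults 24 weeks,
#'   injections at weeks 1 and 25).
#' @param ... Passed to [simulate_regimen()].
#' @return Optimal release rate, ug/week.
#' @export
optimize_release_rate <- function(physiology, drug, target,
                                  criterion = design_criterion(),
                                  bracket = c(0.02, 10), tol_rel = 1e-3,
                                  duration_wk = 24,
                                  injection_times_wk = c(1, 25), ...) {
  f <- function(rate) {
    sch <- build_ivt_schedule(device_spec(rate, duration_wk,
                                          injection_times_wk))
    min_red_percent(simulate_regimen(physiology, drug, target, sch,
                                     horizon_wk = criterion$horizon, ...),
                    criterion)
  }
  bisect_design(f, bracket, criterion$target_reduction, tol_rel)
}

#' Device-emptying failure sweep
#'
#' For each premature-emptying scenario, releases the full device load at the
#' elevated effective rate, simulates a single injection, evaluates free
#' TNF-alpha in all four locations at the time of the next administration
#' (nominal duration post-dose) and classifies the outcome with
#' [classify_outcome()].
#'
#' @param physiology,drug,target Model inputs.
#' @param device Nominal (optimal) [device_spec()].
#' @param weeks_early_list Integer weeks of premature exhaustion to sweep.
#' @param ... Passed to [simulate_regimen()].
#' @return data.frame: `weeks_early`, `effective_rate_ug_wk`, `category`,
#'   `triggering_location` and the four evaluated concentrations (pM).
#' @export
failure_sweep <- function(physiology, drug, target, device,
                          weeks_early_list = 0:10, ...) {
  stopifnot(inherits(device, "device_spec"))
  inj_wk <- device$injection_times[1]
  eval_wk <- inj_wk + device$duration
  rows <- lapply(weeks_early_list, function(w) {
    dev <- device_spec(device$release_rate, device$duration,
                       injection_times = inj_wk, emptying_weeks_early = w)
    sim <- simulate_regimen(physiology, drug, target,
                            build_ivt_schedule(dev), horizon_wk = eval_wk,
                            ...)
    conc <- vapply(TNF_COMPARTMENTS, function(loc) {
      v <- sim_series(sim, loc, "tnf_free")
      v[length(v)]
    }, numeric(1))
    cls <- classify_outcome(conc)
    out <- data.frame(weeks_early = w,
                      effective_rate_ug_wk = round(dev$effective_rate, 3),
                      category = as.character(cls$category),
                      triggering_location = cls$triggering_location)
    for (loc in TNF_COMPARTMENTS)
      out[[paste0("tnf_", loc, "_pM")]] <- round(conc[[loc]], 3)
    out
  })
  do.call(rbind, rows)
}

#' Local sensitivity of the optimal release rate
#'
#' Perturbs the synthesis factor and/or the drug binding constants by the
#' given fold factors (both directions by default) and re-runs
#' [optimize_release_rate()] for each cell; optimizer failures (e.g. the
#' target leaving the bracket) are recorded as `NA` and the sweep continues.
#'
#' @param physiology,drug,target Model inputs.
#' @param parameters Subset of `"SF"`, `"koff_TNF"`, `"Kd_TNF"`.
#' @param factors Positive multipliers (default 1/10, 1/4, 1/2, 2, 4, 10).
#' @param criterion A [design_criterion()].
#' @param ... Passed to [optimize_release_rate()].
#' @return data.frame: `parameter`, `factor`, `rate_ug_wk`,
#'   `relative_change` vs the nominal optimum.
#' @export
sensitivity_sweep <- function(physiology, drug, target,
                              parameters = c("SF", "koff_TNF", "Kd_TNF"),
                              factors = c(1/10, 1/4, 1/2, 2, 4, 10),
                              criterion = design_criterion(), ...) {
  if (!all(parameters %in% c("SF", "koff_TNF", "Kd_TNF")))
    stop("parameters must be a subset of SF, koff_TNF, Kd_TNF")
  if (any(factors <= 0)) stop("factors must be positive")
  opt_cell <- function(d, tg) {
    tryCatch(optimize_release_rate(physiology, d, tg, criterion, ...),
             error = function(e) NA_real_)
  }
  nominal <- opt_cell(drug, target)
  rows <- list(data.frame(parameter = "nominal", factor = 1,
                          rate_ug_wk = nominal, relative_change = 0))
  for (par in parameters) for (fc in factors) {
    d <- drug; tg <- target
    if (par == "SF") {
      tg <- tryCatch(target_params(target$baseline_conc, target$kdeg_TNF,
                                   target$SF * fc, target$kdeg_complex),
                     error = function(e) NULL)
    } else if (par == "koff_TNF") {
      d <- drug_params(drug$name, drug$MW, drug$Kd_TNF, drug$koff_TNF * fc,
                       drug$radius)
    } else {
      d <- drug_params(drug$name, drug$MW, drug$Kd_TNF * fc, drug$koff_TNF,
                       drug$radius)
    }
    rate <- if (is.null(tg)) NA_real_ else opt_cell(d, tg)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = par, factor = fc, rate_ug_wk = rate,
      relative_change = (rate - nominal) / nominal)
  }
  do.call(rbind, rows)
}
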