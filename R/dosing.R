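#' Intravenous multiple-dose regimen
#'
#' Standard-of-care style regimen: a loading dose (`loading_multiplier` times
#' the maintenance dose) one week after disease induction, then maintenance
#' doses every `interval` weeks starting one week after the loading dose, for
#' as long as a full dosing interval fits before the horizon. The defaults
#' give 26 administrations over one year.
#'
#' @param maintenance_dose Maintenance dose, ug.
#' @param loading_multiplier Multiplier on the first dose (default 2).
#' @param start Time of the loading dose, weeks post-induction (default 1).
#' @param interval Dosing interval, weeks (default 2).
#' @param horizon Treatment horizon, weeks (default 52).
#' @return An object of class `iv_regimen`.
#' @export
iv_regimen <- function(maintenance_dose, loading_multiplier = 2, start = 1,
                       interval = 2, horizon = 52) {
  if (maintenance_dose < 0 || loading_multiplier < 0)
    stop("doses must be >= 0")
  if (interval <= 0) stop("interval must be > 0")
  if (horizon < start) stop("horizon must be >= start")
  structure(list(maintenance_dose = maintenance_dose,
                 loading_multiplier = loading_multiplier,
                 start = start, interval = interval, horizon = horizon),
            class = "iv_regimen")
}

#' Zero-order intravitreal release device
#'
#' A sustained-release formulation injected into the vitreous, releasing drug
#' at a constant rate until its finite load is exhausted. The load is fixed at
#' construction as `release_rate * duration`; a premature-emptying variant
#' (`emptying_weeks_early > 0`) releases the same load at the elevated
#' effective rate `load / (duration - emptying_weeks_early)` and stops early.
#'
#' @param release_rate Nominal release rate, ug/week.
#' @param duration Nominal release duration, weeks (default 24).
#' @param injection_times Device injection times, weeks (default `c(1, 25)`).
#' @param emptying_weeks_early Weeks of premature exhaustion (default 0).
#' @return An object of class `device_spec` with fields `load` (ug),
#'   `effective_rate` (ug/week) and `effective_duration` (weeks).
#' @export
device_spec <- function(release_rate, duration = 24,
                        injection_times = c(1, 25),
                        emptying_weeks_early = 0) {
  if (release_rate < 0) stop("release_rate must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (emptying_weeks_early < 0 || emptying_weeks_early >= duration)
    stop("emptying_weeks_early must lie in [0, duration)")
  if (is.unsorted(injection_times, strictly = TRUE))
    stop("injection_times must be strictly increasing")
  load <- release_rate * duration
  eff_dur <- duration - emptying_weeks_early
  structure(list(release_rate = release_rate, duration = duration,
                 load = load, injection_times = injection_times,
                 emptying_weeks_early = emptying_weeks_early,
                 effective_rate = load / eff_dur,
                 effective_duration = eff_dur),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec> %.4g ug/week x %g weeks (load %.4g ug)\n",
              x$release_rate, x$duration, x$load))
  cat(sprintf("  injections at weeks %s\n",
              paste(x$injection_times, collapse = ", ")))
  if (x$emptying_weeks_early > 0)
    cat(sprintf("  emptying %g weeks early: effective %.4g ug/week over %g weeks\n",
                x$emptying_weeks_early, x$effective_rate,
                x$effective_duration))
  invisible(x)
}

new_schedule <- function(df) {
  df <- df[order(df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$time_h[df$kind == "iv_bolus"]))
    stop("bolus event times must be strictly increasing")
  structure(df, class = c("dose_schedule", "data.frame"))
}

#' Build the IV standard-of-care event schedule
#'
#' @param regimen An [iv_regimen()].
#' @return A `dose_schedule` data.frame with columns `time_h`, `kind`
#'   (`"iv_bolus"`), `amount_ug`, `rate_ug_wk`, `duration_h`.
#' @examples
#' nrow(build_iv_soc_schedule(iv_regimen(24.5)))  # 26 administrations
#' @export
build_iv_soc_schedule <- function(regimen) {
  stopifnot(inherits(regimen, "iv_regimen"))
  times <- regimen$start
  amounts <- regimen$loading_multiplier * regimen$maintenance_dose
  t <- regimen$start + 1
  while (t + regimen$interval <= regimen$horizon + 1e-9) {
    times <- c(times, t)
    amounts <- c(amounts, regimen$maintenance_dose)
    t <- t + regimen$interval
  }
  new_schedule(data.frame(time_h = times * HOURS_PER_WEEK, kind = "iv_bolus",
                          amount_ug = amounts, rate_ug_wk = NA_real_,
                          duration_h = NA_real_))
}

#' Build an intravitreal device event schedule
#'
#' One device-start event per injection time; each device releases at its
#' effective rate for its effective duration (rates of overlapping devices
#' add).
#'
#' @param device A [device_spec()].
#' @return A `dose_schedule` data.frame (kind `"ivt_device_start"`).
#' @export
build_ivt_schedule <- function(device) {
  stopifnot(inherits(device, "device_spec"))
  new_schedule(data.frame(
    time_h = device$injection_times * HOURS_PER_WEEK,
    kind = "ivt_device_start", amount_ug = NA_real_,
    rate_ug_wk = device$effective_rate,
    duration_h = device$effective_duration * HOURS_PER_WEEK))
}

#' Combine dose schedules
#' @param ... `dose_schedule` objects.
#' @return A merged `dose_schedule`.
#' @export
combine_schedules <- function(...) {
  new_schedule(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Effective release rate of a prematurely emptying device
#'
#' Load conservation: a device designed to release `optimal_rate` over
#' `interval` weeks but emptying `weeks_early` weeks before the next
#' administration must have released at
#' `optimal_rate * interval / (interval - weeks_early)`.
#'
#' @param optimal_rate Nominal rate, ug/week.
#' @param interval Nominal release interval, weeks.
#' @param weeks_early Weeks of premature exhaustion, in `[0, interval)`.
#' @return Effective release rate, ug/week.
#' @examples
#' emptying_rate(1.802, 24, 10)  # 3.089
#' @export
emptying_rate <- function(optimal_rate, interval, weeks_early) {
  if (any(weeks_early < 0) || any(weeks_early >= interval))
    stop("weeks_early must lie in [0, interval)")
  optimal_rate * interval / (interval - weeks_early)
}

#' Transient intraocular-pressure perturbation factor
#'
#' Multiplicative factor applied to the posterior-to-anterior flow `Q_VA` and
#' aqueous drainage `Q_AH` after an intravitreal injection, decaying
#' exponentially: `1 + amplitude * exp(-t / tau)`.
#'
#' @param t_since_injection Time since the injection, h (>= 0).
#' @param amplitude Peak fractional increase (0 disables).
#' @param tau Decay time constant, h.
#' @return Multiplicative factor (>= 1 for non-negative amplitude).
#' @export
iop_perturbation_factor <- function(t_since_injection, amplitude, tau) {
  if (tau <= 0) stop("tau must be positive")
  if (any(t_since_injection < 0)) stop("t_since_injection must be >= 0")
  1 + amplitude * exp(-t_since_injection / tau)
}

#' Exhaustion times of the devices in a schedule
#'
#' @param schedule A `dose_schedule`.
#' @return Numeric vector of exhaustion times, h (empty if no devices).
#' @export
detect_device_exhaustion <- function(schedule) {
  dev <- schedule[schedule$kind == "ivt_device_start", , drop = FALSE]
  dev$time_h + dev$duration_h
}

#' Total administered dose over a schedule
#'
#' Sum of all bolus amounts (including loading doses) plus the full load of
#' every device (`rate * duration`).
#'
#' @param schedule A `dose_schedule`.
#' @return Total dose, ug.
#' @export
total_annual_dose <- function(schedule) {
  bol <- schedule$amount_ug[schedule$kind == "iv_bolus"]
  dev <- schedule[schedule$kind == "ivt_device_start", , drop = FALSE]
  sum(bol, na.rm = TRUE) + sum(dev$rate_ug_wk * dev$duration_h /
                                 HOURS_PER_WEEK)
}
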