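#' Empty dose schedule
#' @return A `dose_schedule` with no events (untreated disease course).
#' @export
empty_schedule <- function() {
  new_schedule(data.frame(time_h = numeric(0), kind = character(0),
                          amount_ug = numeric(0), rate_ug_wk = numeric(0),
                          duration_h = numeric(0)))
}

make_grid <- function(breaks, fine_step, coarse_step, fine_window) {
  pts <- numeric(0)
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    fe <- min(a + fine_window, b)
    pts <- c(pts, seq(a, fe, by = fine_step))
    if (fe < b) pts <- c(pts, seq(fe, b, by = coarse_step))
  }
  pts <- sort(unique(c(pts, breaks)))
  pts[c(TRUE, diff(pts) > 1e-9)]
}

#' Event-driven simulation of the disease model
#'
#' Deterministic stiff integration (LSODA) of the ocular TMDD disease model
#' over the study horizon. The run starts `abs(start_wk)` weeks before disease
#' induction at the healthy steady state; at time 0 the synthesis factor
#' switches to its disease value and the flow-recovery couplings take effect.
#' Integration restarts at every bolus, device start, device exhaustion and at
#' induction, so all discontinuities fall on segment boundaries. Identical
#' inputs give identical output.
#'
#' @param physiology An [ocular_physiology()].
#' @param drug A [drug_params()].
#' @param target A [target_params()].
#' @param schedule A `dose_schedule` (default: no treatment).
#' @param horizon_wk Simulation horizon, weeks post-induction.
#' @param start_wk Start time, weeks (negative; default -1).
#' @param rtol,atol Relative / absolute integration tolerances.
#' @param engine `"c"` (compiled, default) or `"r"` (reference R
#'   implementation of the same right-hand side).
#' @param fine_step_h,coarse_step_h,fine_window_h Output grid control: step
#'   within `fine_window_h` after each event, and elsewhere, in h.
#' @return An object of class `tnf_sim`; see [sim_series()],
#'   [as.data.frame.tnf_sim()], [steady_state_average()].
#' @export
simulate_regimen <- function(physiology, drug, target,
                             schedule = empty_schedule(), horizon_wk = 52,
                             start_wk = -1, rtol = 1e-8, atol = 1e-10,
                             engine = c("c", "r"), fine_step_h = 1,
                             coarse_step_h = 6, fine_window_h = 168) {
  stopifnot(inherits(physiology, "ocular_physiology"),
            inherits(drug, "drug_params"), inherits(target, "target_params"),
            inherits(schedule, "dose_schedule"))
  engine <- match.arg(engine)
  if (start_wk >= 0) stop("start_wk must be negative (pre-induction burn-in)")
  horizon_h <- horizon_wk * HOURS_PER_WEEK
  start_h <- start_wk * HOURS_PER_WEEK
  if (nrow(schedule) > 0 &&
      (min(schedule$time_h) < start_h || max(schedule$time_h) > horizon_h))
    stop("schedule events must lie within [start, horizon]")

  devices <- schedule[schedule$kind == "ivt_device_start", , drop = FALSE]
  boluses <- schedule[schedule$kind == "iv_bolus", , drop = FALSE]
  dev_end <- detect_device_exhaustion(schedule)
  breaks <- sort(unique(c(start_h, 0, schedule$time_h,
                          pmin(dev_end, horizon_h), horizon_h)))
  breaks <- breaks[breaks >= start_h & breaks <= horizon_h]
  grid <- make_grid(breaks, fine_step_h, coarse_step_h, fine_window_h)

  y <- baseline_state(physiology, target, diseased = FALSE)
  rows_t <- numeric(0)
  rows_y <- NULL
  diagnostics <- integer(0)
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    hit <- abs(boluses$time_h - t0) < 1e-9
    if (any(hit))
      y[1] <- y[1] + sum(ug_to_pmol(boluses$amount_ug[hit], drug$MW))
    active <- devices$time_h <= t0 + 1e-9 &
      (devices$time_h + devices$duration_h) >= t1 - 1e-9
    release <- sum(ug_per_week_to_pmol_per_h(devices$rate_ug_wk[active],
                                             drug$MW))
    iop_t0 <- -1e30
    if (physiology$iop_enabled && nrow(devices) > 0) {
      past <- devices$time_h[devices$time_h <= t0 + 1e-9]
      if (length(past) > 0) iop_t0 <- max(past)
    }
    diseased <- t0 >= -1e-9
    pv <- rhs_parms(physiology, drug, target,
                    sf = if (diseased) target$SF else 1,
                    disease_active = diseased,
                    release_pmol_h = release, iop_t0 = iop_t0)
    times <- grid[grid >= t0 - 1e-9 & grid <= t1 + 1e-9]
    times <- sort(unique(c(t0, times, t1)))
    times <- times[c(TRUE, diff(times) > 1e-9)]
    out <- if (engine == "c") {
      deSolve::lsoda(y = unname(y), times = times, func = "ocutmdd_derivs",
                     parms = pv, dllname = "ocutmdd",
                     initfunc = "ocutmdd_initmod", rtol = rtol, atol = atol,
                     maxsteps = 50000)
    } else {
      deSolve::lsoda(y = unname(y), times = times, func = ocular_rhs_r,
                     parms = pv, rtol = rtol, atol = atol, maxsteps = 50000)
    }
    istate <- attr(out, "istate")[1]
    diagnostics <- c(diagnostics, istate)
    if (is.null(istate) || istate < 0 || any(!is.finite(out[, -1])))
      stop("integration failed in segment [", t0, ", ", t1, "] h; ",
           "last good state at t = ", out[nrow(out), 1], ": ",
           paste(signif(out[nrow(out), -1], 6), collapse = " "))
    keep <- if (i < length(breaks) - 1L) seq_len(nrow(out) - 1L)
            else seq_len(nrow(out))
    rows_t <- c(rows_t, out[keep, 1])
    rows_y <- rbind(rows_y, out[keep, -1, drop = FALSE])
    y <- out[nrow(out), -1]
    names(y) <- state_names()
  }
  colnames(rows_y) <- state_names()
  structure(list(time_h = rows_t, amounts = rows_y,
                 physiology = physiology, drug = drug, target = target,
                 schedule = schedule, horizon_wk = horizon_wk,
                 start_wk = start_wk, rtol = rtol, atol = atol,
                 engine = engine, istate = diagnostics),
            class = "tnf_sim")
}

#' @export
print.tnf_sim <- function(x, ...) {
  cat(sprintf("<tnf_sim> %s, %d events, weeks %g to %g, %d time points (engine %s)\n",
              x$drug$name, nrow(x$schedule), x$start_wk, x$horizon_wk,
              length(x$time_h), x$engine))
  for (loc in TNF_COMPARTMENTS) {
    v <- sim_series(x, loc, "tnf_free")
    cat(sprintf("  free TNF %-17s final %8.3g pM  min %8.3g pM\n", loc,
                v[length(v)], min(v)))
  }
  invisible(x)
}

#' Extract one concentration series
#'
#' @param sim A `tnf_sim`.
#' @param location Compartment name (see `COMPARTMENTS`).
#' @param species One of `"drug"`, `"tnf_free"`, `"complex"`, `"tnf_total"`.
#' @return Numeric vector of concentrations (pM) aligned with `sim$time_h`.
#' @export
sim_series <- function(sim, location,
                       species = c("drug", "tnf_free", "complex",
                                   "tnf_total")) {
  species <- match.arg(species)
  if (!location %in% COMPARTMENTS) stop("unknown location '", location, "'")
  V <- sim$physiology$volumes_L[[location]]
  get <- function(prefix) {
    col <- paste0(prefix, "_", location)
    if (!col %in% colnames(sim$amounts))
      stop(species, " is not modelled in ", location)
    sim$amounts[, col] / V
  }
  switch(species,
         drug = get("drug"),
         tnf_free = get("tnf"),
         complex = get("complex"),
         tnf_total = get("tnf") + get("complex"))
}

#' Tidy long-format concentrations
#'
#' @param x A `tnf_sim`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame with columns `time_h`, `compartment`, `species`,
#'   `conc_pM`.
#' @export
as.data.frame.tnf_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- list()
  for (loc in COMPARTMENTS) {
    specs <- if (loc %in% TNF_COMPARTMENTS)
      c("drug", "tnf_free", "complex") else "drug"
    for (sp in specs)
      out[[paste(loc, sp)]] <- data.frame(
        time_h = x$time_h, compartment = loc, species = sp,
        conc_pM = sim_series(x, loc, sp))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

trapz_mean <- function(t, v, t0, t1) {
  if (t1 <= t0) stop("empty averaging window")
  if (t0 < min(t) - 1e-9 || t1 > max(t) + 1e-9)
    stop("window [", t0, ", ", t1, "] h outside simulated grid")
  inside <- t > t0 & t < t1
  tt <- c(t0, t[inside], t1)
  vv <- c(stats::approx(t, v, t0, ties = "ordered")$y, v[inside],
          stats::approx(t, v, t1, ties = "ordered")$y)
  sum(diff(tt) * (head(vv, -1) + vv[-1]) / 2) / (t1 - t0)
}

#' Time-weighted steady-state average concentration
#'
#' Trapezoidal mean of a concentration series over a window. With
#' `window_wk = NULL` the default window is the last complete dosing interval
#' before the horizon (IV) or the last device interval (IVT); see
#' [steady_state_window()].
#'
#' @param sim A `tnf_sim`.
#' @param location Compartment.
#' @param species Series to average (default free TNF-alpha).
#' @param window_wk Numeric length-2 window in weeks, or `NULL` for the
#'   default.
#' @return Average concentration, pM.
#' @export
steady_state_average <- function(sim, location, species = "tnf_free",
                                 window_wk = NULL) {
  if (is.null(window_wk))
    window_wk <- steady_state_window(sim$schedule, sim$horizon_wk)
  trapz_mean(sim$time_h, sim_series(sim, location, species),
             window_wk[1] * HOURS_PER_WEEK, window_wk[2] * HOURS_PER_WEEK)
}

#' Default steady-state averaging window
#'
#' IV schedules: the last complete dosing interval before the horizon
#' (weeks 50-52 under the standard-of-care defaults). Device schedules: the
#' last device's release interval (weeks 25-49 under the defaults). Untreated
#' runs: the final week.
#'
#' @param schedule A `dose_schedule`.
#' @param horizon_wk Horizon, weeks.
#' @return Numeric length-2 vector of weeks.
#' @export
steady_state_window <- function(schedule, horizon_wk) {
  dev <- schedule[schedule$kind == "ivt_device_start", , drop = FALSE]
  bol <- schedule[schedule$kind == "iv_bolus", , drop = FALSE]
  if (nrow(dev) > 0) {
    last <- which.max(dev$time_h)
    t0 <- dev$time_h[last] / HOURS_PER_WEEK
    t1 <- min(t0 + dev$duration_h[last] / HOURS_PER_WEEK, horizon_wk)
    return(c(t0, t1))
  }
  if (nrow(bol) >= 2) {
    tb <- sort(bol$time_h) / HOURS_PER_WEEK
    interval <- tb[length(tb)] - tb[length(tb) - 1]
    return(c(tb[length(tb)], min(tb[length(tb)] + interval, horizon_wk)))
  }
  c(horizon_wk - 1, horizon_wk)
}
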