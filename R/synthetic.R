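#' Jittered physiology variant
#'
#' Applies independent multiplicative lognormal jitter (median = shipped
#' default, so the geometric mean over many draws matches the default) to
#' every volume, flow and clearance of the calibrated default physiology.
#' Fractions (`f_Schlemm`, `sigma_AH`) are jittered on the logit scale and so
#' remain in (0, 1). Reproducible given the seed.
#'
#' @param seed Integer RNG seed.
#' @param jitter_cv Coefficient of variation of the jitter (0 returns the
#'   defaults exactly).
#' @return An [ocular_physiology()].
#' @export
sample_physiology <- function(seed, jitter_cv = 0.2) {
  if (jitter_cv < 0) stop("jitter_cv must be >= 0")
  base <- default_physiology()
  if (jitter_cv == 0) return(base)
  sdlog <- sqrt(log(1 + jitter_cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, sdlog))
  jit_frac <- function(x) stats::plogis(stats::qlogis(x) +
                                          stats::rnorm(length(x), 0, sdlog))
  jp <- function(p, frac = FALSE) {
    f <- if (frac) jit_frac else jit
    modulated_process(f(p$healthy_value), f(p$disease_value),
                      p$coupling_location, fraction = frac)
  }
  ocular_physiology(
    q_ah = jp(base$q_ah), q_av = jp(base$q_av), q_va = jp(base$q_va),
    f_schlemm = jp(base$f_schlemm, frac = TRUE),
    sigma_ah = jp(base$sigma_ah, frac = TRUE),
    volumes_ml = jit(base$volumes_L * 1000),
    Q_ICB_uLh = jit(base$Q_ICB * 1e6), PS_ICB_uLh = jit(base$PS_ICB * 1e6),
    L_ICB_uLh = jit(base$L_ICB * 1e6), CL_sys_mLh = jit(base$CL_sys * 1e3),
    iop_enabled = base$iop_enabled, iop_amplitude = base$iop_amplitude,
    iop_tau_h = base$iop_tau_h)
}

#' Noisy synthetic observations of a simulated series
#'
#' Samples the deterministic model output at the requested times and applies
#' multiplicative lognormal error: `obs = model * exp(e)`,
#' `e ~ N(0, sqrt(log(1 + cv^2)))`. The returned set carries the generating
#' context (physiology, drug, target, schedule, horizon) so that
#' [recover_parameters()] can re-simulate.
#'
#' @param sim A `tnf_sim`.
#' @param times Sampling times, h (must lie within the simulated grid).
#' @param location,species Series observed.
#' @param cv Observation coefficient of variation (>= 0).
#' @param seed Integer RNG seed.
#' @return An `observation_set`: data.frame-like list with `time_h`,
#'   `conc_pM`, plus noise/context metadata.
#' @export
noisy_observations <- function(sim, times, location, species = "tnf_free",
                               cv = 0.2, seed = 1) {
  if (cv < 0) stop("cv must be >= 0")
  if (any(times < min(sim$time_h) - 1e-9 | times > max(sim$time_h) + 1e-9))
    stop("observation times outside the simulated grid")
  model <- stats::approx(sim$time_h, sim_series(sim, location, species),
                         xout = times, ties = "ordered")$y
  sdlog <- sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  obs <- model * exp(stats::rnorm(length(times), 0, sdlog))
  structure(list(time_h = times, conc_pM = obs, location = location,
                 species = species, cv = cv, seed = seed,
                 context = list(physiology = sim$physiology, drug = sim$drug,
                                target = sim$target, schedule = sim$schedule,
                                horizon_wk = sim$horizon_wk,
                                start_wk = sim$start_wk)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d observations of %s %s (cv %g, seed %d)\n",
              length(x$time_h), x$species, x$location, x$cv, x$seed))
  invisible(x)
}

apply_free_params <- function(context, theta) {
  ctx <- context
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (nm == "SF") {
      tg <- ctx$target
      ctx$target <- target_params(tg$baseline_conc, tg$kdeg_TNF, v,
                                  tg$kdeg_complex)
    } else if (nm == "CL_sys") {
      ctx$physiology$CL_sys <- v * 1e-3  # mL/h -> L/h
    } else if (nm == "release_rate") {
      dev <- ctx$schedule$kind == "ivt_device_start"
      if (!any(dev)) stop("schedule has no device to re-rate")
      ctx$schedule$rate_ug_wk[dev] <- v
    } else stop("unknown free parameter '", nm, "'")
  }
  ctx
}

#' Least-squares parameter recovery from synthetic observations
#'
#' Fits a documented identifiable subset of parameters (`"SF"`, `"CL_sys"`
#' in mL/h, `"release_rate"` in ug/week) by minimising the sum of squared
#' log-concentration residuals, re-simulating the model at every objective
#' evaluation. One free parameter uses golden-section search
#' ([stats::optimize()]); several use box-constrained quasi-Newton
#' ([stats::optim()] L-BFGS-B). Non-convergence is flagged, not thrown.
#'
#' @param obs An `observation_set` from [noisy_observations()].
#' @param free Character vector of free parameter names.
#' @param lower,upper Bounds, in the order of `free`.
#' @param rtol,atol Simulation tolerances during fitting.
#' @return List: `estimates` (named), `rss`, `converged`, `n_obs`.
#' @export
recover_parameters <- function(obs, free = "SF", lower, upper,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(obs, "observation_set"))
  pos <- obs$conc_pM > 0
  objective <- function(par) {
    theta <- as.list(par)
    names(theta) <- free
    ctx <- apply_free_params(obs$context, theta)
    sim <- try(simulate_regimen(ctx$physiology, ctx$drug, ctx$target,
                                ctx$schedule, horizon_wk = ctx$horizon_wk,
                                start_wk = ctx$start_wk, rtol = rtol,
                                atol = atol, fine_step_h = 2,
                                coarse_step_h = 12), silent = TRUE)
    if (inherits(sim, "try-error")) return(1e10)
    pred <- stats::approx(sim$time_h, sim_series(sim, obs$location,
                                                 obs$species),
                          xout = obs$time_h, ties = "ordered")$y
    if (any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
    sum((log(pred[pos]) - log(obs$conc_pM[pos]))^2)
  }
  if (length(free) == 1L) {
    fit <- stats::optimize(objective, lower = lower, upper = upper,
                           tol = 1e-4 * (upper - lower))
    est <- stats::setNames(fit$minimum, free)
    rss <- fit$objective
    converged <- is.finite(rss) && rss < 1e10
  } else {
    start <- sqrt(lower * upper)
    fit <- try(stats::optim(start, objective, method = "L-BFGS-B",
                            lower = lower, upper = upper), silent = TRUE)
    if (inherits(fit, "try-error")) {
      est <- stats::setNames(rep(NA_real_, length(free)), free)
      rss <- NA_real_
      converged <- FALSE
    } else {
      est <- stats::setNames(fit$par, free)
      rss <- fit$value
      converged <- fit$convergence == 0 && is.finite(rss) && rss < 1e10
    }
  }
  list(estimates = est, rss = rss, converged = converged,
       n_obs = length(obs$time_h))
}
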