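CONFIG_KEYS <- c("drug", "physiology", "target", "regimen", "horizon_weeks",
                 "solver", "seed", "output_dir")

cfg_num <- function(x, key, min = -Inf, max = Inf) {
  if (is.null(x)) return(NULL)
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) ||
      any(x < min) || any(x > max))
    stop("config key '", key, "': expected number(s) in [", min, ", ", max,
         "], got ", deparse(x))
  x
}

#' Parse and validate a run configuration file
#'
#' Reads a structured YAML configuration, rejects unknown top-level keys,
#' fills defaults and constructs the model objects. Recognised keys:
#' `drug` (a shipped name or a map with `name`, `MW`, `Kd_TNF`, `koff_TNF`),
#' `physiology` (`"default"`, a map `{file: path}` pointing to a physiology
#' YAML, or `{seed:, jitter_cv:}` for a jittered variant), `target`
#' (optional overrides of [target_params()] fields), `regimen` (`type:
#' iv_soc` with `dose_ug`, or `type: ivt` with `release_rate_ug_wk`, or
#' `type: none`), `horizon_weeks`, `solver` (`rtol`, `atol`), `seed`,
#' `output_dir`.
#'
#' @param path Path to the YAML file.
#' @return An object of class `run_config`: validated fields plus constructed
#'   `drug`, `physiology`, `target` and `schedule` objects.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  drug <- if (is.character(raw$drug)) {
    default_drug_params(raw$drug)
  } else if (is.list(raw$drug)) {
    drug_params(raw$drug$name,
                cfg_num(raw$drug$MW, "drug.MW", min = 1e-12),
                cfg_num(raw$drug$Kd_TNF, "drug.Kd_TNF", min = 1e-12),
                cfg_num(raw$drug$koff_TNF, "drug.koff_TNF", min = 1e-12),
                if (is.null(raw$drug$radius)) NA_real_ else raw$drug$radius)
  } else stop("config key 'drug' is required (name or parameter map)")

  phys_spec <- if (is.null(raw$physiology)) "default" else raw$physiology
  physiology <- if (identical(phys_spec, "default")) {
    default_physiology()
  } else if (is.list(phys_spec) && !is.null(phys_spec$file)) {
    read_physiology_yaml(phys_spec$file)
  } else if (is.list(phys_spec) && !is.null(phys_spec$seed)) {
    sample_physiology(as.integer(phys_spec$seed),
                      cfg_num(phys_spec$jitter_cv %||% 0.2,
                              "physiology.jitter_cv", min = 0))
  } else stop("config key 'physiology': expected \"default\", {file:} or {seed:}")

  tg <- raw$target %||% list()
  target <- target_params(
    baseline_conc = cfg_num(tg$baseline_conc %||% 1, "target.baseline_conc",
                            min = 1e-12),
    kdeg_TNF = cfg_num(tg$kdeg_TNF %||% 0.223, "target.kdeg_TNF",
                       min = 1e-12),
    SF = cfg_num(tg$SF %||% 7, "target.SF", min = 1),
    kdeg_complex = cfg_num(tg$kdeg_complex %||% 0.18, "target.kdeg_complex",
                           min = 1e-12))

  horizon <- cfg_num(raw$horizon_weeks %||% 52, "horizon_weeks", min = 1)
  reg <- raw$regimen %||% list(type = "none")
  if (is.null(reg$type) ||
      !reg$type %in% c("iv_soc", "ivt", "none"))
    stop("config key 'regimen.type': expected iv_soc, ivt or none")
  schedule <- switch(
    reg$type,
    none = empty_schedule(),
    iv_soc = build_iv_soc_schedule(iv_regimen(
      cfg_num(reg$dose_ug, "regimen.dose_ug", min = 0),
      loading_multiplier = cfg_num(reg$loading_multiplier %||% 2,
                                   "regimen.loading_multiplier", min = 0),
      start = cfg_num(reg$start_week %||% 1, "regimen.start_week", min = 0),
      interval = cfg_num(reg$interval_weeks %||% 2, "regimen.interval_weeks",
                         min = 1e-9),
      horizon = horizon)),
    ivt = build_ivt_schedule(device_spec(
      cfg_num(reg$release_rate_ug_wk, "regimen.release_rate_ug_wk", min = 0),
      duration = cfg_num(reg$duration_weeks %||% 24, "regimen.duration_weeks",
                         min = 1e-9),
      injection_times = cfg_num(reg$injection_weeks %||% c(1, 25),
                                "regimen.injection_weeks", min = 0),
      emptying_weeks_early = cfg_num(reg$emptying_weeks_early %||% 0,
                                     "regimen.emptying_weeks_early",
                                     min = 0))))

  solver <- raw$solver %||% list()
  structure(list(
    drug = drug, physiology = physiology, target = target,
    schedule = schedule, regimen_type = reg$type, horizon_weeks = horizon,
    rtol = cfg_num(solver$rtol %||% 1e-8, "solver.rtol", min = 1e-15),
    atol = cfg_num(solver$atol %||% 1e-10, "solver.atol", min = 0),
    seed = as.integer(raw$seed %||% 1L),
    output_dir = raw$output_dir %||% ".",
    source_path = path), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a physiology YAML file
#'
#' Format mirrors the shipped `inst/extdata/default_physiology.yaml`.
#'
#' @param path YAML path.
#' @return An [ocular_physiology()].
#' @export
read_physiology_yaml <- function(path) {
  if (!file.exists(path)) stop("physiology file not found: ", path)
  y <- yaml::read_yaml(path)
  mp <- function(key, coupling, fraction = FALSE) {
    v <- y[[key]]
    if (is.null(v$healthy) || is.null(v$disease))
      stop("physiology key '", key, "' must have healthy and disease values")
    modulated_process(v$healthy, v$disease, coupling, fraction)
  }
  iop <- y$iop %||% list()
  ocular_physiology(
    q_ah = mp("q_ah_uLh", "AH"),
    q_av = mp("q_av_uLh", "ICB_interstitial"),
    q_va = mp("q_va_uLh", "ICB_interstitial"),
    f_schlemm = mp("f_schlemm", "AH", fraction = TRUE),
    sigma_ah = mp("sigma_ah", "ICB_plasma", fraction = TRUE),
    volumes_ml = unlist(y$volumes_ml),
    Q_ICB_uLh = cfg_num(y$Q_ICB_uLh, "Q_ICB_uLh", min = 0),
    PS_ICB_uLh = cfg_num(y$PS_ICB_uLh, "PS_ICB_uLh", min = 0),
    L_ICB_uLh = cfg_num(y$L_ICB_uLh, "L_ICB_uLh", min = 0),
    CL_sys_mLh = cfg_num(y$CL_sys_mLh, "CL_sys_mLh", min = 0),
    iop_enabled = iop$enabled %||% TRUE,
    iop_amplitude = iop$amplitude %||% 0.2,
    iop_tau_h = iop$tau_h %||% 24)
}

#' Run a configured simulation and write its outputs
#'
#' Executes [simulate_regimen()] under a parsed configuration and writes
#' tidy results, the event log, a per-location summary and a run log (config
#' checksum, package version, seed) into `out_dir`.
#'
#' @param config A `run_config` from [parse_config()].
#' @param out_dir Output directory (created if missing).
#' @return The `tnf_sim`, invisibly; files are listed in
#'   `<out_dir>/manifest.csv`.
#' @export
run_from_config <- function(config, out_dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_regimen(config$physiology, config$drug, config$target,
                          config$schedule, horizon_wk = config$horizon_weeks,
                          rtol = config$rtol, atol = config$atol)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary_df <- regimen_summary(sim)
  tables <- list(results = as.data.frame(sim),
                 events = as.data.frame(config$schedule),
                 summary = summary_df)
  write_summary_tables(tables, out_dir)
  log_df <- data.frame(
    key = c("config_md5", "config_path", "package_version", "seed",
            "timepoints"),
    value = c(unname(tools::md5sum(config$source_path)), config$source_path,
              as.character(utils::packageVersion("ocutmdd")),
              as.character(config$seed), as.character(length(sim$time_h))))
  utils::write.csv(log_df, file.path(out_dir, "run_log.csv"),
                   row.names = FALSE)
  invisible(sim)
}

#' Write named summary tables as CSV with a checksum manifest
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if missing).
#' @return The manifest data.frame (`file`, `md5`, `bytes`), invisibly
#'   written to `manifest.csv`.
#' @export
write_summary_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
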