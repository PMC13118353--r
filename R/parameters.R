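#' @useDynLib ocutmdd, .registration = TRUE
NULL

# canonical compartment order used throughout (drug in all five,
# TNF-alpha and complex only in the first four)
COMPARTMENTS <- c("venous_plasma", "ICB_plasma", "ICB_interstitial", "AH", "vitreous")
TNF_COMPARTMENTS <- COMPARTMENTS[1:4]
HOURS_PER_WEEK <- 168

#' Anti-TNF-alpha antibody parameters
#'
#' Physicochemical and target-binding constants for one monoclonal antibody.
#' The association rate constant is derived as `kon = koff_TNF / Kd_TNF`
#' (units 1/(h*pM)).
#'
#' @param name Drug identifier.
#' @param MW Molecular weight, g/mol.
#' @param Kd_TNF Drug/TNF-alpha dissociation constant, pM. `Inf` disables
#'   binding (kon = 0).
#' @param koff_TNF First-order complex dissociation rate constant, 1/h.
#' @param radius Hydrodynamic radius, nm (documentation only).
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(name, MW, Kd_TNF, koff_TNF, radius = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(MW) || length(MW) != 1L || !is.finite(MW) || MW <= 0)
    stop("MW must be a positive finite number (g/mol)")
  if (!is.numeric(Kd_TNF) || length(Kd_TNF) != 1L || is.na(Kd_TNF) || Kd_TNF <= 0)
    stop("Kd_TNF must be positive (pM)")
  if (!is.numeric(koff_TNF) || length(koff_TNF) != 1L || !is.finite(koff_TNF) ||
      koff_TNF <= 0)
    stop("koff_TNF must be positive and finite (1/h)")
  structure(
    list(name = name, MW = MW, radius = radius,
         Kd_TNF = Kd_TNF, koff_TNF = koff_TNF,
         kon_TNF = kon_from(koff_TNF, Kd_TNF)),
    class = "drug_params")
}

#' Association rate constant from dissociation constants
#'
#' `kon = koff / Kd`, the second-order association rate constant implied by a
#' measured dissociation rate and equilibrium constant.
#'
#' @param koff_TNF First-order dissociation rate, 1/h.
#' @param Kd_TNF Equilibrium dissociation constant, pM (`Inf` gives 0).
#' @return Association rate constant, 1/(h*pM).
#' @examples
#' kon_from(0.335, 18)   # golimumab, ~0.0186
#' @export
kon_from <- function(koff_TNF, Kd_TNF) {
  if (!is.numeric(koff_TNF) || !is.numeric(Kd_TNF) ||
      any(is.na(koff_TNF)) || any(is.na(Kd_TNF)) ||
      any(koff_TNF <= 0) || any(Kd_TNF <= 0))
    stop("koff_TNF and Kd_TNF must be positive")
  koff_TNF / Kd_TNF
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s\n", x$name))
  cat(sprintf("  MW      %g g/mol\n", x$MW))
  cat(sprintf("  Kd      %g pM\n", x$Kd_TNF))
  cat(sprintf("  koff    %g 1/h\n", x$koff_TNF))
  cat(sprintf("  kon     %.4g 1/(h*pM)\n", x$kon_TNF))
  invisible(x)
}

#' TNF-alpha turnover and complex parameters
#'
#' The soluble target is produced at a zero-order rate and degraded
#' first-order; systemic inflammation multiplies the healthy synthesis rate by
#' the synthesis factor `SF`, so the pathological steady-state concentration is
#' `SF * baseline_conc`.
#'
#' @param baseline_conc Healthy free TNF-alpha concentration, pM.
#' @param kdeg_TNF First-order TNF-alpha degradation rate, 1/h.
#' @param SF Dimensionless synthesis factor (>= 1).
#' @param kdeg_complex First-order drug-TNF-alpha complex degradation rate, 1/h.
#' @return An object of class `target_params`.
#' @export
target_params <- function(baseline_conc = 1, kdeg_TNF = 0.223, SF = 7,
                          kdeg_complex = 0.18) {
  vals <- c(baseline_conc, kdeg_TNF, SF, kdeg_complex)
  if (any(!is.finite(vals)) || baseline_conc <= 0 || kdeg_TNF <= 0 ||
      kdeg_complex <= 0)
    stop("target parameters must be positive and finite")
  if (SF < 1) stop("SF must be >= 1")
  structure(
    list(baseline_conc = baseline_conc, kdeg_TNF = kdeg_TNF, SF = SF,
         kdeg_complex = kdeg_complex,
         pathological_conc = SF * baseline_conc),
    class = "target_params")
}

#' @export
print.target_params <- function(x, ...) {
  cat("<target_params>\n")
  cat(sprintf("  baseline      %g pM\n", x$baseline_conc))
  cat(sprintf("  kdeg TNF      %g 1/h (t1/2 %.2f h)\n", x$kdeg_TNF,
              log(2) / x$kdeg_TNF))
  cat(sprintf("  SF            %g (pathological %g pM)\n", x$SF,
              x$pathological_conc))
  cat(sprintf("  kdeg complex  %g 1/h\n", x$kdeg_complex))
  invisible(x)
}

#' Disease-modulated physiological process
#'
#' A flow or fraction that is reduced/altered under anterior uveitis and
#' recovers linearly with the local drug-TNF-alpha complex fraction at its
#' anatomical coupling location (see [recovery_value()]).
#'
#' @param healthy_value Physiological value (flow or dimensionless fraction).
#' @param disease_value Value under full disease (zero complexation).
#' @param coupling_location One of `"AH"`, `"ICB_interstitial"`, `"ICB_plasma"`:
#'   the compartment whose complex fraction drives recovery.
#' @param fraction Logical; if `TRUE` both values must lie in \[0, 1\].
#' @return An object of class `modulated_process`.
#' @export
modulated_process <- function(healthy_value, disease_value,
                              coupling_location = c("AH", "ICB_interstitial",
                                                    "ICB_plasma"),
                              fraction = FALSE) {
  coupling_location <- match.arg(coupling_location)
  if (!is.finite(healthy_value) || !is.finite(disease_value))
    stop("healthy_value and disease_value must be finite")
  if (fraction &&
      (healthy_value < 0 || healthy_value > 1 ||
       disease_value < 0 || disease_value > 1))
    stop("fractional process values must lie in [0, 1]")
  if (!fraction && (healthy_value < 0 || disease_value < 0))
    stop("flows must be non-negative")
  structure(
    list(healthy_value = healthy_value, disease_value = disease_value,
         coupling_location = coupling_location, fraction = fraction),
    class = "modulated_process")
}

#' Ocular and systemic physiology
#'
#' Container for the five disease-modulated processes, compartment volumes and
#' systemic transfer parameters of the reduced five-compartment topology
#' (venous plasma, iris-ciliary-body (ICB) plasma, ICB interstitial fluid,
#' aqueous humour (AH), vitreous). Flows are supplied in uL/h, volumes in mL
#' and clearance in mL/h; they are stored internally in L/h and L so that
#' amounts in pmol give concentrations in pM.
#'
#' @param q_ah,q_av,q_va [modulated_process()] flows, uL/h: aqueous-humour
#'   drainage, anterior-to-posterior and posterior-to-anterior bulk flows.
#' @param f_schlemm,sigma_ah [modulated_process()] fractions: fraction of AH
#'   drainage via Schlemm's canal (to venous blood) and the reflection
#'   coefficient at the ICB vascular/aqueous interface.
#' @param volumes_ml Named numeric vector of compartment fluid volumes in mL
#'   for `venous_plasma`, `ICB_plasma`, `ICB_interstitial`, `AH`, `vitreous`.
#' @param Q_ICB_uLh ICB plasma perfusion flow, uL/h.
#' @param PS_ICB_uLh Permeability-surface product for ICB plasma/interstitial
#'   exchange, uL/h.
#' @param L_ICB_uLh Lymph flow ICB interstitial to venous plasma, uL/h.
#' @param CL_sys_mLh Lumped first-order systemic clearance of drug from venous
#'   plasma, mL/h.
#' @param iop_enabled Apply the transient intraocular-pressure perturbation to
#'   `Q_VA` and `Q_AH` after each intravitreal injection?
#' @param iop_amplitude,iop_tau_h Perturbation amplitude (dimensionless) and
#'   decay time constant (h); see [iop_perturbation_factor()].
#' @return An object of class `ocular_physiology`.
#' @export
ocular_physiology <- function(q_ah, q_av, q_va, f_schlemm, sigma_ah,
                              volumes_ml, Q_ICB_uLh, PS_ICB_uLh, L_ICB_uLh,
                              CL_sys_mLh, iop_enabled = TRUE,
                              iop_amplitude = 0.2, iop_tau_h = 24) {
  for (p in list(q_ah, q_av, q_va, f_schlemm, sigma_ah))
    if (!inherits(p, "modulated_process"))
      stop("q_ah, q_av, q_va, f_schlemm and sigma_ah must be modulated_process objects")
  if (!f_schlemm$fraction || !sigma_ah$fraction)
    stop("f_schlemm and sigma_ah must be fractional processes")
  if (q_ah$coupling_location != "AH" || f_schlemm$coupling_location != "AH")
    stop("Q_AH and f_Schlemm must couple to the AH complex fraction")
  if (q_av$coupling_location != "ICB_interstitial" ||
      q_va$coupling_location != "ICB_interstitial")
    stop("Q_AV and Q_VA must couple to the ICB interstitial complex fraction")
  if (sigma_ah$coupling_location != "ICB_plasma")
    stop("sigma_AH must couple to the ICB plasma complex fraction")
  if (!all(COMPARTMENTS %in% names(volumes_ml)))
    stop("volumes_ml must name all of: ", paste(COMPARTMENTS, collapse = ", "))
  volumes_ml <- volumes_ml[COMPARTMENTS]
  if (any(!is.finite(volumes_ml)) || any(volumes_ml <= 0))
    stop("all compartment volumes must be positive")
  flows <- c(Q_ICB_uLh, PS_ICB_uLh, L_ICB_uLh, CL_sys_mLh)
  if (any(!is.finite(flows)) || any(flows < 0))
    stop("Q_ICB, PS_ICB, L_ICB and CL_sys must be non-negative")
  if (iop_tau_h <= 0) stop("iop_tau_h must be positive")
  structure(
    list(q_ah = q_ah, q_av = q_av, q_va = q_va,
         f_schlemm = f_schlemm, sigma_ah = sigma_ah,
         volumes_L = volumes_ml / 1000,
         Q_ICB = Q_ICB_uLh * 1e-6,    # L/h
         PS_ICB = PS_ICB_uLh * 1e-6,  # L/h
         L_ICB = L_ICB_uLh * 1e-6,    # L/h
         CL_sys = CL_sys_mLh * 1e-3,  # L/h
         iop_enabled = isTRUE(iop_enabled),
         iop_amplitude = iop_amplitude, iop_tau_h = iop_tau_h),
    class = "ocular_physiology")
}

#' @export
print.ocular_physiology <- function(x, ...) {
  cat("<ocular_physiology> (flows uL/h, volumes uL)\n")
  fmt <- function(p) sprintf("healthy %.4g / disease %.4g  [%s]",
                             p$healthy_value * if (p$fraction) 1 else 1,
                             p$disease_value, p$coupling_location)
  cat("  Q_AH      ", fmt(x$q_ah), "\n")
  cat("  Q_AV      ", fmt(x$q_av), "\n")
  cat("  Q_VA      ", fmt(x$q_va), "\n")
  cat("  f_Schlemm ", fmt(x$f_schlemm), "\n")
  cat("  sigma_AH  ", fmt(x$sigma_ah), "\n")
  cat("  volumes   ", paste(sprintf("%s=%.3g", COMPARTMENTS,
                                    x$volumes_L * 1e6), collapse = " "), "\n")
  cat(sprintf("  Q_ICB %.3g  PS_ICB %.3g  L_ICB %.3g uL/h;  CL_sys %.3g mL/h\n",
              x$Q_ICB * 1e6, x$PS_ICB * 1e6, x$L_ICB * 1e6, x$CL_sys * 1e3))
  cat(sprintf("  IOP perturbation: %s (amplitude %g, tau %g h)\n",
              if (x$iop_enabled) "enabled" else "disabled",
              x$iop_amplitude, x$iop_tau_h))
  invisible(x)
}

#' Shipped drug parameter sets
#'
#' Published binding and size constants for the three IgG1-related
#' anti-TNF-alpha monoclonal antibodies considered.
#'
#' @param name One of `"adalimumab"`, `"golimumab"`, `"infliximab"`.
#' @return A [drug_params()] object.
#' @export
default_drug_params <- function(name) {
  tab <- list(
    adalimumab = list(MW = 144190, Kd = 127, koff = 0.576, radius = 5.04),
    golimumab  = list(MW = 146940, Kd = 18,  koff = 0.335, radius = 5.08),
    infliximab = list(MW = 144190, Kd = 44,  koff = 0.720, radius = 5.04))
  if (!is.character(name) || length(name) != 1L || !(name %in% names(tab)))
    stop("unknown drug '", paste(name, collapse = ","),
         "'; options: ", paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  drug_params(name, MW = p$MW, Kd_TNF = p$Kd, koff_TNF = p$koff,
              radius = p$radius)
}

#' Shipped TNF-alpha parameters
#'
#' Baseline 1 pM, degradation 0.223 1/h, synthesis factor 7 (pathological
#' level 7 pM) and complex degradation 0.18 1/h.
#'
#' @return A [target_params()] object.
#' @export
default_target_params <- function() target_params()

#' Calibrated default physiology
#'
#' The ocular/systemic physiological values are calibrated defaults, not
#' direct experimental measurements: volumes and the healthy aqueous-humour
#' turnover are taken from typical rat ocular physiology, and the remaining
#' transfer parameters were tuned once so that intravenous dosing yields
#' ICB-interstitial drug exposure roughly 14-fold above aqueous humour while
#' intravitreal devices invert that gradient. See the methods vignette.
#'
#' @return An [ocular_physiology()] object.
#' @export
default_physiology <- function() {
  ocular_physiology(
    q_ah = modulated_process(26, 13, "AH"),                    # uL/h, a = 2
    q_av = modulated_process(1.0, 1.0 / 3, "ICB_interstitial"),# uL/h, b = 3
    q_va = modulated_process(0.5, 0.5 / 3, "ICB_interstitial"),# uL/h, c = 3
    f_schlemm = modulated_process(0.93, 0.70, "AH", fraction = TRUE),
    sigma_ah = modulated_process(0.93, 0.60, "ICB_plasma", fraction = TRUE),
    volumes_ml = c(venous_plasma = 10, ICB_plasma = 0.002,
                   ICB_interstitial = 0.010, AH = 0.025, vitreous = 0.054),
    Q_ICB_uLh = 300, PS_ICB_uLh = 2.4, L_ICB_uLh = 0.1,
    CL_sys_mLh = 0.027,
    iop_enabled = TRUE, iop_amplitude = 0.2, iop_tau_h = 24)
}
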