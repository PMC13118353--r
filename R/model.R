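#' Convert a device release rate to model units
#'
#' Bridges device release rates (ug/week) to the pmol/h amounts used by the
#' ODE system: `rate * 1e6 / MW / 168`.
#'
#' @param rate Release rate, ug/week (>= 0).
#' @param MW Molecular weight, g/mol.
#' @return Release rate in pmol/h.
#' @export
ug_per_week_to_pmol_per_h <- function(rate, MW) {
  if (any(!is.finite(MW)) || any(MW <= 0)) stop("MW must be positive")
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rate must be >= 0")
  rate * 1e6 / MW / HOURS_PER_WEEK
}

ug_to_pmol <- function(ug, MW) ug * 1e6 / MW

#' Net TNF-alpha turnover rate
#'
#' Zero-order synthesis scaled by the synthesis factor minus first-order
#' degradation: `SF * kdeg * A_healthy - kdeg * A`, where the healthy synthesis
#' rate is recovered from the healthy steady state (`ksyn = kdeg * A_healthy`).
#'
#' @param A_TNF Free TNF-alpha amount, pmol.
#' @param SF Synthesis factor (>= 1).
#' @param kdeg Degradation rate, 1/h.
#' @param A_TNF_healthy Healthy steady-state amount, pmol.
#' @return Net rate, pmol/h.
#' @export
tnf_turnover_rate <- function(A_TNF, SF, kdeg, A_TNF_healthy) {
  if (any(A_TNF < 0)) stop("A_TNF must be >= 0")
  if (kdeg <= 0 || A_TNF_healthy <= 0 || SF < 1)
    stop("require kdeg > 0, A_TNF_healthy > 0, SF >= 1")
  SF * kdeg * A_TNF_healthy - kdeg * A_TNF
}

#' Disease-state recovery of a modulated process
#'
#' Linear interpolation between the full-disease and healthy value driven by
#' the local complex fraction `A_complex / TNF_total`: at zero complexation the
#' process sits at its disease value, at complete complexation it is fully
#' restored.
#'
#' @param process A [modulated_process()].
#' @param complex_fraction Complex fraction in \[0, 1\] at the process's
#'   coupling location (defined as 0 when `TNF_total` = 0).
#' @return The modulated process value.
#' @export
recovery_value <- function(process, complex_fraction) {
  stopifnot(inherits(process, "modulated_process"))
  if (any(!is.finite(complex_fraction)) || any(complex_fraction < 0) ||
      any(complex_fraction > 1))
    stop("complex_fraction must lie in [0, 1]")
  process$disease_value +
    (process$healthy_value - process$disease_value) * complex_fraction
}

#' Mass-action TMDD fluxes in one compartment
#'
#' Full (non-approximated) 1:1 target-mediated drug disposition: binding at
#' `kon * A_TNF * (A_drug / V)` with the free-drug concentration in pM,
#' dissociation at `koff * A_complex`, and complex degradation at
#' `kdeg_complex * A_complex` (degradation removes both binding partners).
#'
#' @param A_drug,A_TNF,A_complex Amounts, pmol.
#' @param V Compartment volume, L.
#' @param drug A [drug_params()].
#' @param target A [target_params()].
#' @return Named numeric vector `c(binding, dissociation, degradation)`,
#'   pmol/h.
#' @export
tmdd_rates <- function(A_drug, A_TNF, A_complex, V, drug, target) {
  if (!is.numeric(V) || V <= 0) stop("V must be positive (L)")
  if (any(c(A_drug, A_TNF, A_complex) < 0)) stop("amounts must be >= 0")
  c(binding = drug$kon_TNF * A_TNF * (A_drug / V),
    dissociation = drug$koff_TNF * A_complex,
    degradation = target$kdeg_complex * A_complex)
}

# --- internal parameter-vector layout shared by the R and C right-hand sides
# indices (1-based R / 0-based C):
#  1-5   volumes L (venous, ICB_plasma, ICB_interstitial, AH, vitreous)
#  6-7   Q_AH healthy/disease (L/h)
#  8-9   Q_AV healthy/disease
# 10-11  Q_VA healthy/disease
# 12-13  f_Schlemm healthy/disease
# 14-15  sigma_AH healthy/disease
# 16     Q_ICB   17 PS_ICB   18 L_ICB   19 CL_sys (L/h)
# 20     kon (1/(h*pM))  21 koff  22 kdeg_complex  23 kdeg_TNF (1/h)
# 24     SF in effect  25 disease_active (0/1)  26 baseline_conc (pM)
# 27     release rate into vitreous (pmol/h)
# 28     time of last IVT injection (h; < -1e29 disables the IOP factor)
# 29     IOP amplitude  30 IOP tau (h)
rhs_parms <- function(physiology, drug, target, sf, disease_active,
                      release_pmol_h, iop_t0 = -1e30) {
  c(physiology$volumes_L,
    physiology$q_ah$healthy_value * 1e-6, physiology$q_ah$disease_value * 1e-6,
    physiology$q_av$healthy_value * 1e-6, physiology$q_av$disease_value * 1e-6,
    physiology$q_va$healthy_value * 1e-6, physiology$q_va$disease_value * 1e-6,
    physiology$f_schlemm$healthy_value, physiology$f_schlemm$disease_value,
    physiology$sigma_ah$healthy_value, physiology$sigma_ah$disease_value,
    physiology$Q_ICB, physiology$PS_ICB, physiology$L_ICB, physiology$CL_sys,
    drug$kon_TNF, drug$koff_TNF, target$kdeg_complex, target$kdeg_TNF,
    sf, as.numeric(disease_active), target$baseline_conc,
    release_pmol_h, iop_t0, physiology$iop_amplitude, physiology$iop_tau_h,
    use.names = FALSE)
}

# state layout: y[1:5] drug, y[6:9] free TNF (venous, ICB_plasma,
# ICB_interstitial, AH), y[10:13] complex (same order)
IDX_DRUG <- 1:5
IDX_TNF <- 6:9
IDX_CX <- 10:13

#' Assembled model right-hand side (reference R implementation)
#'
#' Time derivatives of all 13 state amounts (free drug in five compartments;
#' free TNF-alpha and drug-TNF-alpha complex in venous plasma, ICB plasma, ICB
#' interstitial fluid and aqueous humour). Used directly by
#' `simulate_regimen(engine = "r")` and as the reference against which the
#' compiled C right-hand side is tested. TNF-alpha is stationary (no
#' inter-compartment transport); only free drug moves with the ocular flows.
#'
#' @param t Time, h.
#' @param y State vector, pmol.
#' @param parms Parameter vector from the internal layout (see source).
#' @return List with the derivative vector, as required by [deSolve::lsoda()].
#' @keywords internal
#' @export
ocular_rhs_r <- function(t, y, parms) {
  p <- parms
  V <- p[1:5]
  frac <- function(i_tnf, i_cx) {
    tot <- y[i_tnf] + y[i_cx]
    if (tot <= 0) return(0)
    min(max(y[i_cx] / tot, 0), 1)
  }
  if (p[25] > 0.5) {  # disease active: processes interpolate disease->healthy
    f_ah <- frac(9, 13)    # AH
    f_ici <- frac(8, 12)   # ICB interstitial
    f_icp <- frac(7, 11)   # ICB plasma
    rec <- function(h, d, f) d + (h - d) * f
    Q_AH <- rec(p[6], p[7], f_ah)
    f_schlemm <- rec(p[12], p[13], f_ah)
    Q_AV <- rec(p[8], p[9], f_ici)
    Q_VA <- rec(p[10], p[11], f_ici)
    sigma <- rec(p[14], p[15], f_icp)
  } else {
    Q_AH <- p[6]; f_schlemm <- p[12]; Q_AV <- p[8]; Q_VA <- p[10]
    sigma <- p[14]
  }
  if (p[28] > -1e29 && t >= p[28]) {  # post-injection IOP transient
    m <- 1 + p[29] * exp(-(t - p[28]) / p[30])
    Q_VA <- Q_VA * m
    Q_AH <- Q_AH * m
  }
  C <- y[IDX_DRUG] / V  # pM
  kon <- p[20]; koff <- p[21]; kdegc <- p[22]; kdeg <- p[23]
  sf <- p[24]; base <- p[26]
  bind <- kon * y[IDX_TNF] * C[1:4]
  diss <- koff * y[IDX_CX]
  dtnf <- sf * kdeg * base * V[1:4] - kdeg * y[IDX_TNF] - bind + diss
  dcx <- bind - diss - kdegc * y[IDX_CX]
  ddrug <- numeric(5)
  ddrug[1] <- p[16] * (C[2] - C[1]) + f_schlemm * Q_AH * C[4] +
    p[18] * C[3] - p[19] * C[1]
  ddrug[2] <- p[16] * (C[1] - C[2]) - Q_AH * (1 - sigma) * C[2] +
    p[17] * (C[3] - C[2])
  ddrug[3] <- p[17] * (C[2] - C[3]) + (1 - f_schlemm) * Q_AH * C[4] -
    p[18] * C[3]
  ddrug[4] <- Q_AH * (1 - sigma) * C[2] + Q_VA * C[5] -
    (Q_AV + Q_AH) * C[4]
  ddrug[5] <- p[27] + Q_AV * C[4] - Q_VA * C[5]
  ddrug[1:4] <- ddrug[1:4] - bind + diss
  dy <- c(ddrug, dtnf, dcx)
  if (any(!is.finite(dy)))
    stop("non-finite derivative at t = ", t, "; state: ",
         paste(signif(y, 6), collapse = " "))
  list(dy)
}

#' Equilibrium free-target concentration for 1:1 binding
#'
#' Closed-form root of the binding quadratic for total drug `D`, total target
#' `T` and dissociation constant `Kd` (all pM):
#' `C_free = T - ((D + T + Kd) - sqrt((D + T + Kd)^2 - 4 D T)) / 2`.
#' Used as the analytic counterpart of the zero-net-binding condition of
#' [tmdd_rates()] in a closed compartment without turnover.
#'
#' @param D,T_,Kd Total drug, total target and dissociation constant, pM.
#' @return Free target concentration, pM.
#' @export
equilibrium_free_target <- function(D, T_, Kd) {
  cx <- ((D + T_ + Kd) - sqrt((D + T_ + Kd)^2 - 4 * D * T_)) / 2
  T_ - cx
}

baseline_state <- function(physiology, target, diseased = FALSE) {
  sf <- if (diseased) target$SF else 1
  y <- numeric(13)
  y[IDX_TNF] <- sf * target$baseline_conc * physiology$volumes_L[1:4]
  names(y) <- state_names()
  y
}

state_names <- function() {
  c(paste0("drug_", COMPARTMENTS), paste0("tnf_", TNF_COMPARTMENTS),
    paste0("complex_", TNF_COMPARTMENTS))
}
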