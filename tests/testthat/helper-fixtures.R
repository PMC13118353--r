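# shared fixtures: shipped parameter sets and small helper constructors
phys_default <- default_physiology()
target_default <- default_target_params()
drug_ada <- default_drug_params("adalimumab")
drug_goli <- default_drug_params("golimumab")
drug_inf <- default_drug_params("infliximab")

# physiology with all transport and elimination switched off: an isolated
# set of closed compartments (used for conservation and closed-form checks)
phys_closed <- function(CL_sys_mLh = 0) {
  ocular_physiology(
    q_ah = modulated_process(0, 0, "AH"),
    q_av = modulated_process(0, 0, "ICB_interstitial"),
    q_va = modulated_process(0, 0, "ICB_interstitial"),
    f_schlemm = modulated_process(0.9, 0.7, "AH", fraction = TRUE),
    sigma_ah = modulated_process(0.9, 0.6, "ICB_plasma", fraction = TRUE),
    volumes_ml = c(venous_plasma = 10, ICB_plasma = 0.002,
                   ICB_interstitial = 0.010, AH = 0.025, vitreous = 0.054),
    Q_ICB_uLh = 0, PS_ICB_uLh = 0, L_ICB_uLh = 0, CL_sys_mLh = CL_sys_mLh,
    iop_enabled = FALSE)
}

# drug with binding disabled (infinite Kd => kon = 0)
drug_inert <- drug_params("inert", MW = 144190, Kd_TNF = Inf, koff_TNF = 0.5)

# independent oracle for the 1:1 binding equilibrium: root of the mass-action
# residual (Tfree * Dfree = Kd * Cx) found numerically, no closed form used
equilibrium_oracle <- function(D, T_, Kd) {
  g <- function(cx) (T_ - cx) * (D - cx) - Kd * cx
  cx <- stats::uniroot(g, c(0, min(D, T_)), tol = 1e-14)$root
  T_ - cx
}

# dense grid-scan oracle: smallest grid value meeting the design target
grid_scan_oracle <- function(f, lo, hi, target, by = 0.1) {
  xs <- seq(lo, hi, by = by)
  ok <- vapply(xs, function(x) f(x) >= target, logical(1))
  if (!any(ok)) stop("oracle: target not reached on grid")
  xs[which(ok)[1]]
}
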