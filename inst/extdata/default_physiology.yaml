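# Calibrated default ocular/systemic physiology for the rat anterior-uveitis
# disease model. These values are calibrated defaults, NOT direct experimental
# measurements: volumes and healthy aqueous turnover follow typical rat ocular
# physiology; transfer parameters were tuned once so that IV dosing yields
# ICB-interstitial drug exposure ~14-fold above aqueous humour and
# intravitreal devices invert that gradient. Flows in uL/h, volumes in mL,
# clearance in mL/h.
q_ah_uLh:          # aqueous humour drainage (disease = healthy / a, a = 2)
  healthy: 26
  disease: 13
q_av_uLh:          # anterior-to-posterior bulk flow (b = 3)
  healthy: 1.0
  disease: 0.3333333333333333
q_va_uLh:          # posterior-to-anterior bulk flow (c = 3)
  healthy: 0.5
  disease: 0.16666666666666666
f_schlemm:         # fraction of drainage via Schlemm's canal (to blood)
  healthy: 0.93
  disease: 0.70
sigma_ah:          # reflection coefficient at the ICB vascular/aqueous interface
  healthy: 0.93
  disease: 0.60
volumes_ml:
  venous_plasma: 10
  ICB_plasma: 0.002
  ICB_interstitial: 0.010
  AH: 0.025
  vitreous: 0.054
Q_ICB_uLh: 300     # ICB plasma perfusion
PS_ICB_uLh: 2.4    # plasma <-> interstitial permeability-surface product
L_ICB_uLh: 0.1     # interstitial -> venous lymph flow
CL_sys_mLh: 0.027  # lumped first-order systemic clearance
iop:
  enabled: true
  amplitude: 0.2
  tau_h: 24
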