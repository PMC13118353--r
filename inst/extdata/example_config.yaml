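# Minimal run configuration: golimumab intravitreal sustained-release device
# at its optimal release rate, two injections per year.
drug: golimumab
physiology: default
regimen:
  type: ivt
  release_rate_ug_wk: 0.979
  duration_weeks: 24
  injection_weeks: [1, 25]
horizon_weeks: 52
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
seed: 1
output_dir: ocutmdd-out
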