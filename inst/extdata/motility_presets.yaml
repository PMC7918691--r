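# Frozen run-and-pause kinetic presets, version 1.
# Calibrated once by grid search so that 1,000 simulated 120-s tracks per
# preset reproduce the published state statistics:
#   mobile   mito: mean speed ~0.7 um/s, net displacement ~9 um
#   mobile   lyso: mean speed ~1.1 um/s, net displacement ~14 um
#   immobile mito: mean speed ~0.4 um/s, net displacement ~5 um
#   immobile lyso: mean speed ~0.4 um/s, net displacement ~5 um
# Units: speeds um/s, jitter um per step, diameters log-um.
mobile_mito:
  run_speed_mean: 0.9615
  run_speed_sd: 0.30
  pause_fraction: 0.30
  reversal_prob_per_step: 0.09017
  jitter_sd: 0.02
  diameter_meanlog: -0.223
  diameter_sdlog: 0.20
mobile_lyso:
  run_speed_mean: 1.5342
  run_speed_sd: 0.45
  pause_fraction: 0.30
  reversal_prob_per_step: 0.09500
  jitter_sd: 0.02
  diameter_meanlog: -0.511
  diameter_sdlog: 0.20
immobile_mito:
  run_speed_mean: 0.8705
  run_speed_sd: 0.30
  pause_fraction: 0.60
  reversal_prob_per_step: 0.08726
  jitter_sd: 0.02
  diameter_meanlog: -0.223
  diameter_sdlog: 0.20
immobile_lyso:
  run_speed_mean: 0.8705
  run_speed_sd: 0.30
  pause_fraction: 0.60
  reversal_prob_per_step: 0.08726
  jitter_sd: 0.02
  diameter_meanlog: -0.511
  diameter_sdlog: 0.20
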