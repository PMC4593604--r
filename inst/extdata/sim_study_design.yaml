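# Synthetic plate-study design mirroring the standard VMR assay shape:
# 3 wild-type strains x 7 stages (3-9 dpf) x 2 biological repeats on
# 96-well plates, 30 min recorded dark then 3 consecutive 30-min
# Light-On / Light-Off trials at 30 frames/s. All effect sizes and the
# noise model are synthetic modeling choices, not estimates from any
# experimental dataset. Pass to: vmr simulate --config sim_study_design.yaml
strains:
  AB:   {baseline: 0.14, resp_mod: 1.0}
  TL:   {baseline: 0.12, resp_mod: 0.9}
  TLAB: {baseline: 0.10, resp_mod: 0.8}
stages: [3, 4, 5, 6, 7, 8, 9]
stage_mult: {"3": 0.70, "4": 0.80, "5": 0.90, "6": 1.00, "7": 1.10, "8": 1.20, "9": 1.30}
stage_resp: {"3": 0.20, "4": 0.60, "5": 0.90, "6": 1.00, "7": 1.10, "8": 1.15, "9": 1.20}
rows: 8
cols: 12
location_coef: 0.0
n_bio_rep: 2
bio_rep_sd: 0.01
tech_rep_sd: 0.01
kernel_on:  {peak: 0.25, decay: 0.15, sustained: 0.05}
kernel_off: {peak: 0.45, decay: 0.80, sustained: 0.15}
animal_sd: 0.02
ar1_rho: 0.5
innovation_sd: 0.03
fps: 30
recorded_dark_s: 1800
n_trials: 3
phase_len_s: 1800
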