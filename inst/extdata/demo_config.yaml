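# Demonstration configuration for run_pipeline(): an end-to-end run on
# synthetic data at desk scale.
seed: 42
cohort:
  n_plants: 9
  length_sd_cm: 1.0
kinematics:
  grid_dx_mm: 0.1
  cell_grid_mm: [0, 12, 0.1]
  rel_cessation_frac: 0.05
water:
  ww: {tissue: "N2 root tip", psi_w: -0.25, psi_s: -0.85}
  wd: {tissue: "N2 root tip", psi_w: -0.75, psi_s: -1.35}
  turgor_tolerance_mpa: 0.05
metabolome:
  n_reps: 3
  cv: 0.10
  missing_rate: 0.05
  p_cut: 0.05
  q_cut: 0.10
  fc_cut: 1.5
transcriptome:
  tiers: [2, 1]
  tf_threshold: 1.2
  tf_min_count: 5
pathways:
  gmt: pathways_toy.gmt
  edges: pathways_toy_edges.tsv
  logp_gate: 2
  impact_gate: 0.1
  fdr_gate: 0.1
concordance:
  enzyme_map: enzyme_map_synthetic.tsv
  anchors: transcript_anchors_synthetic.tsv
  dat_threshold: 1
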