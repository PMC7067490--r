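# Example run configuration for run_workflow(): generates a small synthetic
# MKN1 dataset, fits four kinetic rates and simulates two prediction
# experiments. All stages are seeded.
seed: 7
outdir: egfrsig_example_run
stages: [generate, fit, predict]
variant:
  feedback_erk_to_ras: false
  ligand: EGF
design:
  cell_lines: [MKN1]
  tc_times: [0, 5, 15, 60, 240]
  egf_doses: null
  replicates: 2
estimation:
  n_starts: 5
  free_kinetic: [k_degR, k_int, k_erkOff, k_aktOff]
  profile_scalings: true
  maxiter: 100
predictions:
  experiments: [met-inhibitor, pi3k-wt]
  inhibitor_doses: [0, 0.1, 1, 10]
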