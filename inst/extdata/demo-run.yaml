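# Demo pipeline configuration: two synthetic specimens per orientation,
# both damage criteria, no FE stage (enable fe for the full study).
seed: 7
criteria: [von_mises, max_normal_strain]
out_dir: meniscusCDM-demo
synth:
  n_per_orientation: 2
  noise_frac: 0.01
fit:
  damage_budget: 150
fe:
  enabled: false
  refine_factor: 1
  n_steps: 12
  target_stretch_longitudinal: 1.18
  target_stretch_transverse: 1.45
  export_vtk: true
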