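# Demo configuration: noiseless tube phantom (in vitro arm) plus a swelling
# brain-slice phantom (in vivo arm), quantified end to end.
seed: 1
phantom:
  geometry: tube
  dim: [12, 12, 40]
  voxel_mm: [0.4, 0.4, 0.5]
  times_h: [1.5, 3.0, 6.0, 12.0, 24.0]
  volume_uL: [40, 42, 46, 50, 54]
  D_true: 7.0e-11
  sigma: 0
phantom_brain:
  geometry: brain
  dim: [24, 20, 12]
  voxel_mm: [0.25, 0.25, 0.5]
  times_h: [1.5, 3.0, 6.0, 12.0, 24.0]
  gel_uL: 5.3
  volume_uL: [5.3, 5.5, 6.0, 7.0, 8.0]
  gel_semiaxes_mm: [1.1, 1.1, 1.3]
  C0_mM: 0.02
  D_true: 1.0e-10
  sigma: 0
calibration:
  r1_true: 93.2
  T1_0: 2.5
  conc_mg_ml: [0.093, 0.19, 0.37, 0.74]
  noise_frac: 0.01
segmentation:
  tolerance: 0.15
  rim_depth: 1
kinetics:
  window_h: [0.0, 24.0]
  geometry: one_sided
  prefactor: 4
  temperature_K: 310.15
  mw_kda: 74
  diameter_nm: 7.2
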