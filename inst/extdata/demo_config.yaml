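# Demo study configuration for run_pipeline(): a simulated compact phantom
# cohort with three lesioned patients and one longitudinal patient.
seed: 1
output_dir: fcanomaly-demo
phantom:
  size: compact
model:
  t: 150
  lambda: 1.0
  eta: 0.5
  sigma: 1.0
controls:
  n: 12
patients:
  - id: P01
    hemisphere: L
    gamma: 0.8
    mode: functional
  - id: P02
    hemisphere: R
    gamma: 0.6
    mode: functional
  - id: P03
    hemisphere: L
    gamma: 0.5
    mode: spatial
    tau: 6
analysis:
  anomaly_threshold: -2.3
  exclusion_fwhm: 3
longitudinal:
  enabled: true
  hemisphere: L
  n_perm: 2000
  min_cm3: 0.3
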