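# Example pipeline configuration for run_pipeline(): generate a small
# synthetic cohort and run the full analysis into ./beta2hr-results.
generator:
  n_patients: 12
  days_per_patient: 90
  mesor: 70
  amplitude: 5
  hr_noise_sd: 6
  laba_offset: 0.8
  laba_frac: 0.7
  exercise_coupling_prob: 0.5
out_dir: beta2hr-results
seed: 42
wear_min_minutes: 10080
n_control: 50
min_control_days: 10
step_filter: true
threshold: 5
span: 0.15
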