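# Example cohort configuration for vfnet::read_cohort_config().
# Every key is optional; omitted keys keep the documented defaults of
# cohort_config(). Unknown keys are rejected.

# subjects per group (three-group design)
group_sizes:
  HC: 29
  TLE-HS: 30
  TLE-NHS: 28

# planted connectivity effects: additive correlation-scale offsets on
# the edges between seed_region and targets (null targets = the other
# members of the seed region's cortex). subject_sd jitters the offset
# per subject.
effects:
  HC:
    seed_region: L.aITG
    offset: 0.0
  TLE-HS:
    seed_region: L.aITG
    offset: -0.25
  TLE-NHS:
    seed_region: L.aITG
    offset: 0.15
  subject_sd: 0.05

# baseline block correlation structure
base_within: 0.4
base_between: 0.1

# noise model
noise:
  ar: 0.3              # AR(1) coefficient of the latent signal, in (-1, 1)
  obs_sd: 0.5          # white observation noise SD
  drift_amp: 0.5       # low-frequency drift amplitude
  drift_period_s: 128  # drift period, seconds
  nuisance_load: 0.3   # loading of WM/CSF-like channels on every region
  n_nuisance: 2
  motion_sd: 0.02      # random-walk step SD of the 6 motion parameters
  outlier_prob: 0.01   # per-frame probability of a global spike
  spike_amp: 6         # spike amplitude, SD units

# per-cortex task response amplitudes (signal units per unit HRF);
# negative values model task deactivation
task_amp:
  left_frontal: 0.8
  right_frontal: 0.3
  left_temporal: -0.5
  other: 0.1

# covariate distributions
covariates:
  age_mean: {HC: 28, TLE-HS: 29, TLE-NHS: 30}
  age_sd: 8
  edu_mean: 12
  edu_sd: 3
  moca_mean: {HC: 28.5, TLE-HS: 26, TLE-NHS: 26}
  moca_sd: 2
  p_male: 0.5

# behavioural score model: score = intercept + slope * seed-region mean
# connectivity + N(0, sd)
scores:
  vfc: {intercept: 20, slope: 20}
  vfp: {intercept: 28, slope: 40}
  vfs: {intercept: 40, slope: 10}
  sd: 6

seed: 20260101
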