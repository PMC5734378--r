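# Example synthetic-experiment configuration (all values settable; see
# ?experiment_config).  Two genotypes: a control-like line with a twice-daily
# visual-gain rhythm and a clock-mutant-like line with a long unimodal rhythm
# and nocturnal locomotor phenotype.
seed: 1
ct_times: [0, 4, 8, 12, 16, 20, 24, 28, 32, 36, 40, 44]
n_flies_per_ct: 2
n_trials: 18
trial_duration_s: 2
n_flies_activity: 16
n_days_ld: 3
n_days_dd: 9
stages: [ssvep, activity]
cascade:
  photoreceptor_gain: 10
  lamina_gain: 0.1
  medulla_gain: 0.05
  mix_weights: [1, 0.5, 0.25]
  noise_sd_mv: 0.2
genotypes:
  control:
    photoreceptor:
      mesor: 1.0
      components:
        - amplitude: 0.3
          period_h: 14.6
          peak_ct_h: 6
    activity:
      baseline_rate: 10
      ld_peaks:
        - zt_h: 0
          height: 1
        - zt_h: 12
          height: 1
      dd_period_h: 24.4
      rhythmic_fraction: 0.69
  clock_mutant:
    photoreceptor:
      mesor: 1.0
      components:
        - amplitude: 0.3
          period_h: 25.2
          peak_ct_h: 4
    activity:
      baseline_rate: 10
      lights_off_step: 0.6
      dd_period_h: 25.2
      rhythmic_fraction: 0.166
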