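# Example end-to-end pipeline configuration.
# Scaled-down cohort: 5 subjects, 30 train days + 5 test days each.
scenario:
  n_days: 35
  meals_per_day: 3
  meal_size_mean: 60
  meal_size_cv: 0.10        # intra-day meal-size variability
  meal_time_std: 20         # minutes
  boluses_per_day_range: [1, 5]
  sensor_noise_sd: 3        # mg/dL, AR(1) correlated
  seed: 20240101
cohort:
  n_subjects: 5
  physiology_cv: 0.1        # inter-subject parameter jitter
split:
  train_days: 30
  test_days: 5
train:
  learning_rate: 0.001
  rmsprop_decay: 0.9
  batch_size: 512
  max_epochs: 30
  patience: 5
  seed: 1
methods: [drnn, arx]
transfer: false
out_dir: glucodrnn-output
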