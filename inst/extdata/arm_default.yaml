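# Gravity-neutral arm: published simulation parameters with the package's
# calibrated noise defaults (crank-turning condition).
plant:
  mass: 1.5            # kg
  lever_arm: 0.35      # m
  damping: 30          # N m s/rad
  gravity_mode: gravity_neutral
controller:
  architecture: model_iii
  k_c: 65              # N m/rad
  delay: 0.100         # s
  noise_velocity_sd: 0.01   # rad/sqrt(s)
  noise_force_sd: 0.25      # N m sqrt(s)
task:
  task: crank
  reference_velocity: 0.471238898038469   # rad/s (0.075 rev/s)
  duration: 400        # s
  dt: 0.0005           # s
  output_rate: 100     # Hz
  n_trials: 200
  seed: 1
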