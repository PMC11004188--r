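# Upright stance (inverted pendulum): published simulation parameters with
# the package's calibrated noise and intermittent-controller defaults
# (quiet-standing condition). k_c exceeds mgL = 735.75 N m/rad.
plant:
  mass: 75             # kg
  lever_arm: 1         # m
  damping: 226         # N m s/rad
  gravity_mode: inverted_pendulum
controller:
  architecture: model_iii
  k_c: 883             # N m/rad
  delay: 0.100         # s
  noise_velocity_sd: 0.001  # rad/sqrt(s)
  noise_force_sd: 0.2       # N m sqrt(s)
  intermittent:
    threshold: 0.05          # rad
    peak_velocity: 0.0167    # rad/s (x6 closed-loop DC amplification in position)
    pulse_sd: 0.1            # s
task:
  task: quiet_standing
  reference_velocity: 0
  duration: 400        # s
  dt: 0.0005           # s
  output_rate: 100     # Hz
  n_trials: 200
  seed: 1
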