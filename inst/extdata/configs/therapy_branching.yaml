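# Calibrate thresholds on the branching preset, then plan and run a
# MI-maximizing curriculum under the estimated constraints.
env: branching
thresholds:
  family: constant
  so: {value: 5}
  a: {value: 5}
therapy:
  q: 0.1
  n_calibration_steps: 250
  gain_floor: 0.02
seed: 9
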