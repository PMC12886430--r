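# One deterministic 8-state stimulus chain; a learn-policy agent memorizes it.
env: chain
agent:
  policy: learn
thresholds:
  family: lognormal
  so: {meanlog: 1.386, sdlog: 0.25}
  a: {meanlog: 1.386, sdlog: 0.25}
  schedule: per_step
n_steps: 120
seed: 6
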