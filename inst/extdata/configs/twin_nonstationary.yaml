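# Matched-seed digital twins: constrain vs passive in a novelty-injecting
# environment, both starting from a fully memorized base environment.
env: nonstationary
twin:
  policy_a: constrain
  policy_b: passive
  pretrain: true
n_steps: 150
n_reps: 10
seed: 5
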