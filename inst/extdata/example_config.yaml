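# example run configuration: slow-absorption reference day under the
# default patient, comparing the feedforward-augmented controller
controller: rlff
seed: 7
scenario:
  tau_class: slow
uncertainty:
  cho_sd_frac: 0.46
  time_sd_min: 2
  n_reps: 100
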