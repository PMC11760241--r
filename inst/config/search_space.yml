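# Default hyperparameter search space for the multi-branch CNN.
# Edit freely; types: uniform, loguniform, integer, categorical.
learning_rate:
  type: loguniform
  lo: 1.0e-4
  hi: 1.0e-2
dropout:
  type: uniform
  lo: 0.0
  hi: 0.5
n_filters:
  type: integer
  lo: 8
  hi: 64
kernel_size:
  type: integer
  lo: 2
  hi: 8
fc_width:
  type: integer
  lo: 16
  hi: 128
batch_size:
  type: categorical
  choices: [16, 32, 64]
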