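# Example run configuration for `strainkit generate`
image:
  height: 64
  width: 64
counts:
  n_pairs: 300
protocol:
  ramp: 3
  hold: 5
  relax: 3
noise:
  speckle_sd: [0.0, 0.12]
  gauss_sd: [0.0, 0.04]
  gain: [0.92, 1.08]
  offset: [-0.04, 0.04]
deformation:
  tension: [0.01, 0.16]
  compression: [-0.16, -0.01]
  rigid_shift: [-5, 5]
seed: 1
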