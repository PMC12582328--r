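{
  "cuticle_swc": "example_cuticle.swc",
  "dendrite_swc": "example_dendrite.swc",
  "dendrite_orientation": "tip_to_constriction",
  "soma_com": [0.2, 0, -4.179886],
  "cuticle_base_point": [0.2, 0, 1.8]
}
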