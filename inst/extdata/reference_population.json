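{
  "preset": "preset-A",
  "n": 1000,
  "seed": 20200425,
  "digest": "f9cb8aeb50cb14c43a4b5b257f2b402a",
  "note": "MD5 over event ages quantized to 1e-9 years; see population_digest()."
}
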