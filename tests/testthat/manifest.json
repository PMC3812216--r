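{
  "command": "nonsense",
  "scenario": "healthy",
  "seed": 1,
  "dt": 0.0005,
  "settle": 120,
  "parameter_hash": "00d6e05d",
  "package_version": "0.1.0"
}
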