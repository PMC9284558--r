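{
  "fidelity": "detailed",
  "design": {
    "s_star_length": 7,
    "mismatch": {"present": true},
    "conc_gates": 100,
    "conc_reporters": 150,
    "conc_inputs": 90
  },
  "schedule": {
    "species": ["A", "B"],
    "time": [0, 600],
    "amount": [90, 90],
    "t_end": 15000
  },
  "solver": {"rtol": 1e-8, "atol": 1e-12, "sample_dt": 1}
}
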