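{
  "rotatable_bonds": {"mean": 5.692308, "sd": 8.769231, "n": 4},
  "molecular_weight": {"mean": 311.136667, "sd": 233.833333, "n": 4},
  "complexity": {"mean": 416.514953, "sd": 502.803738, "n": 4},
  "tpsa": {"mean": 62.7, "sd": 60.0, "n": 4},
  "xlogp": {"mean": 2.576534, "sd": 3.304450, "n": 4}
}
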