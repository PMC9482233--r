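{
  "items": ["EX1", "EX2", "EX3", "EX4", "EX5", "EX6", "EX7", "EX8", "MD1", "MD2", "MD3", "MD4", "MD5", "CI1", "CI2", "CI3", "CI4", "CI5", "EI1", "EI2", "EI3", "EI4", "EI5"],
  "subscales": ["EX", "EX", "EX", "EX", "EX", "EX", "EX", "EX", "MD", "MD", "MD", "MD", "MD", "CI", "CI", "CI", "CI", "CI", "EI", "EI", "EI", "EI", "EI"],
  "n_categories": 5,
  "min_code": 1,
  "max_code": 5
}
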