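# small demonstration grid: overstatement at two heterogeneity levels
alpha: 0.05
reps: 100
grid:
  s: [5, 10]
  ratio: [0.2]
  theta: [0]
  tau2: [0, 0.5]
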