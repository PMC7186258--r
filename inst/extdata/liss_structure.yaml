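# Example panel configuration: the 22-indicator / 6-factor personality
# structure (self-esteem, pessimism, optimism, life satisfaction, positive
# and negative affect) measured over three waves, with the SE2 between-level
# residual variance fixed to zero.
kind: panel
waves: 3
identification: loadings
residual: chol
factors:
  SE: [SE1, SE2, SE3]
  Pes: [Pes1, Pes2, Pes3]
  Opt: [Opt1, Opt2, Opt3]
  LS: [LS1, LS2, LS3, LS4, LS5]
  PA: [PA1, PA2, PA3, PA4]
  "NA": [NA1, NA2, NA3, NA4]
fixed_between_residual: [SE2]
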