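# Clonal-dominance simulation: decelerating seeding, random clone fitness.
immigration:
  form: power_law
  r0: 10
  gamma: -0.5
  weights: distinct
fitness:
  type: uniform
  min: 0.35
  max: 1
simulation:
  horizon: 20
  seed: 1
  lambda: 1
  grid_step: 0.1
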