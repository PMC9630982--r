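# Isolation-with-migration model: an ancestral deme A splits into X and Y
# 100 generations ago; Y later grows exponentially; X and Y exchange
# migrants symmetrically while they coexist.
description: Isolation-with-migration model with exponential growth in Y.
time_units: generations
defaults:
  epoch:
    start_size: 1000
demes:
  - name: A
    description: ancestral deme
    epochs:
      - end_time: 100
  - name: X
    ancestors: [A]
  - name: Y
    ancestors: [A]
    epochs:
      - end_time: 50
      - end_size: 3000
migrations:
  - demes: [X, Y]
    rate: 1.0e-4
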