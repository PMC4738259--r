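# Strong-attractant protocol: nodes (2,2) and (3,5) of the 5x5 array at a
# net 500 units/cell/step over run-clock steps [500, 2500). Weights in the
# schedule are deviations from the 5-unit node baseline.
seed: 1
run_steps: 3500
schedule:
  - {node: 7, weight: 495, from: 500, to: 2500}
  - {col: 3, row: 5, weight: 495, from: 500, to: 2500}
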