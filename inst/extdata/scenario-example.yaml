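# reduced smoke grid: 5-item questionnaire, three shapes, null and medium effect
ng: [50, 100]
j: [5]
gamma: [0, 0.5]
shape: [U, J, L]
reps: 200
seed: 1
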