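# Default synthetic-participant generator settings: the two-urn interview
# design (26 participants, 10 draws without replacement), credences linear
# in the objective posterior and the L_2-rescaled Good scores.
n_participants: 26
n_draws: 10
coefficients: [0.33, 0.40, 0.24, -0.13]
noise_sd: 0.08
judgment_noise_sd: 0.1
measure: G3
seed: 2026
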