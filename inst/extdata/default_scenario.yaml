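# Illustrative semi-Markov remission-relapse scenario (months scale).
# Weibull shape/scale per transition; death clock runs from therapy start;
# censoring is uniform over the follow-up window.
n: 100
achieve:   {shape: 1.3, scale: 12}
lose:      {shape: 0.9, scale: 160}
reachieve: {shape: 1.2, scale: 9}
death:     {shape: 1.1, scale: 400}
censor_low: 0
censor_high: 120
max_depth: 100
unit: months
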