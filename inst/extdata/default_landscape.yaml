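# Default virtual-arrowhead landscape.
# Calibrated with scripts/calibrate_landscape.R so that the 10,000-agent
# win-stay/lose-shift learning curve yields optimal exploration counts
# tau* = 12 (unrepaid/asocial) and tau* = 22 (repaid) at T = 50, L = 5.
optimum:
  length: 85
  width: 95
  thickness: 90
weights:
  length: 0.07
  width: 0.07
  thickness: 0.07
peak: 1000
noise_sd: 5
initial_design:
  length: 30
  width: 40
  thickness: 35
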