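# Benchmark difficulty calibration of the synthetic generator's noise
# model (units: fraction of the normalized pelvis-neck body scale).
# Produced by scripts/calibrate.R; do not edit by hand.
noise_sd: 0.8
outlier_rate: 0.1
outlier_mag: 6.0
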