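# Example normative values for the composite autonomic indices.
# Synthetic representative resting-adult values; every entry is
# `component: [mean, sd]` and may be overridden. See ?hrv_norms.
mean_rr: [900, 110]    # ms
rmssd: [42, 15]        # ms
sd1_nu: [35, 10]       # percent of (SD1 + SD2)
mean_hr: [67, 8]       # bpm
sqrt_si: [9, 3]        # sqrt of Baevsky stress index
sd2_nu: [65, 10]       # percent of (SD1 + SD2)
weights_pnsi: [1, 1, 1]
weights_snsi: [1, 1, 1]
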