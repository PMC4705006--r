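# Example detection-rule configuration for `habsi detect --config ...`.
# Any field of habsi_config() may appear; omitted fields keep defaults.
min_hai_hours: 48
fever_c: 38.0
commensal_window_days: 2
recall_days: 7
polymicrobial_hours: 48
persistent_days: 14
readmit_gap_days: 2
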