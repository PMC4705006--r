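# Example simulation configuration for `habsi simulate --config ...`.
# Any field of cohort_config() may appear; omitted fields keep defaults.
n_patients: 2000
period: ["2012-10-01", "2012-10-31"]
habsi_rate_per_1000_patients: 14.7
contamination_prob: 0.02
revision_after_recall_prob: 0.0005
subtype_mix:
  PRIM_CRBSI: 0.25
  PRIM_CLABSI: 0.20
  PRIM_OTHER: 0.30
  SEC: 0.15
  CSEP: 0.10
seed: 20121001
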