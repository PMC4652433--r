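# Example rule-table configuration. Every field is optional; unspecified
# fields take the package defaults (55, 50, 3, 2, 2 and the default
# recommendation texts).
age_cutoff_primary: 55
age_cutoff_high: 50
amsterdam_min_relatives: 3
amsterdam_min_generations: 2
high_risk_cluster_min: 2
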