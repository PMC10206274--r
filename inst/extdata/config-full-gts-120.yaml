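# Full-scale genomic truncation selection, 120 sires.
scale: full
scenario: GTS
n_sires: 120
n_dams: 1080
n_founders: 2500
burn_in_years: 10
eval_years: 20
n_chr: 39
sites_per_chr: 2250
loci_counts: [250, 1000, 1000]
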