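# Reduced test-scale optimal contribution selection at 65 degrees.
scale: reduced
scenario: GOCS
degrees: 65
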