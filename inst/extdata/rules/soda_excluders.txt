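# Whole-token excluders: any of these tokens in the normalized description
# vetoes the soda label.
diet
lite
light
zero
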