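database	n_sequences	n_ambiguous_mm0
RNAdb2.0	171551	392
piRBase	32826	278
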