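[-0.97, -0.43, 0, 0.44, 0.98]
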