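((A|A:6,B|A:6):4,Q|X:3);
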