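((A|A:6,B|X:2):4,R|A:10);
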