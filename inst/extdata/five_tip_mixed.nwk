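(((A|A:5,B|A:5):3,(C|A:3,D|X:2):5):2,Q|X:6);
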