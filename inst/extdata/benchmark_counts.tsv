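dataset	role	binding	non_binding
TR646	training	15636	298503
TR573	training	14479	145404
TE46	test	956	9911
TE129	test	2240	35275
TE181	test	3208	72050
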