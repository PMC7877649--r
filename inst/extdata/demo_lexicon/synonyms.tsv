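scenario	from	to
cooking pasta	noodle	pasta
cooking pasta	spaghetti	pasta
cooking pasta	burner	stove
cooking pasta	hob	stove
cooking pasta	fill	put
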