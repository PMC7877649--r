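scenario	verb	noun
cooking pasta	boil	water
cooking pasta	pour	pasta
cooking pasta	drain	pasta
cooking pasta	stir	pasta
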