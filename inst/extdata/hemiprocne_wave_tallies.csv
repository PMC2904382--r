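"category","count"
"secondary_only",13
"one_wave",128
"two_waves",32
"three_waves",1
"extra_adjacent",4
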