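"specimen_id","sex","P1","P2","P3","P4","P5","P6","P7","P8","P9","P10"
"58752","F",55,66,78,90,107,121,140,154,162,170
"63244","F",52,60,73,83,97,111,131,142,153,159
"66039","F",55,64,72,88,102,118,133,153,161,163
"68087","F",52,59,71,83,95,112,129,142,155,156
"60252","M",55,64,76,87,100,116,134,145,153,151
"63240","M",49,64,77,87,101,118,134,151,161,162
"68090","M",54,68,74,85,97,109,126,135,152,151
"68099","M",55,63,75,86,101,114,130,143,155,157
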