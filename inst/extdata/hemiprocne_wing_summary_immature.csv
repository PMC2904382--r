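"variant","chain","measure","position","count"
"raw","wing","nodal","S11",0
"raw","wing","nodal","S10",0
"raw","wing","nodal","S9",0
"raw","wing","nodal","S8",0
"raw","wing","nodal","S7",1
"raw","wing","nodal","S6",0
"raw","wing","nodal","S5",0
"raw","wing","nodal","S4",0
"raw","wing","nodal","S3",0
"raw","wing","nodal","S2",0
"raw","wing","nodal","S1",0
"raw","wing","nodal","P1",4
"raw","wing","nodal","P2",0
"raw","wing","nodal","P3",0
"raw","wing","nodal","P4",0
"raw","wing","nodal","P5",0
"raw","wing","nodal","P6",0
"raw","wing","nodal","P7",0
"raw","wing","nodal","P8",0
"raw","wing","nodal","P9",0
"raw","wing","nodal","P10",0
"raw","wing","terminal","S11",0
"raw","wing","terminal","S10",0
"raw","wing","terminal","S9",3
"raw","wing","terminal","S8",1
"raw","wing","terminal","S7",0
"raw","wing","terminal","S6",1
"raw","wing","terminal","S5",0
"raw","wing","terminal","S4",0
"raw","wing","terminal","S3",0
"raw","wing","terminal","S2",1
"raw","wing","terminal","S1",0
"raw","wing","terminal","P1",0
"raw","wing","terminal","P2",0
"raw","wing","terminal","P3",0
"raw","wing","terminal","P4",0
"raw","wing","terminal","P5",0
"raw","wing","terminal","P6",0
"raw","wing","terminal","P7",0
"raw","wing","terminal","P8",0
"raw","wing","terminal","P9",0
"raw","wing","terminal","P10",0
"raw","wing","n_growing","S11",1
"raw","wing","n_growing","S10",3
"raw","wing","n_growing","S9",4
"raw","wing","n_growing","S8",1
"raw","wing","n_growing","S7",1
"raw","wing","n_growing","S6",2
"raw","wing","n_growing","S5",0
"raw","wing","n_growing","S4",0
"raw","wing","n_growing","S3",1
"raw","wing","n_growing","S2",5
"raw","wing","n_growing","S1",2
"raw","wing","n_growing","P1",2
"raw","wing","n_growing","P2",6
"raw","wing","n_growing","P3",5
"raw","wing","n_growing","P4",2
"raw","wing","n_growing","P5",7
"raw","wing","n_growing","P6",8
"raw","wing","n_growing","P7",5
"raw","wing","n_growing","P8",4
"raw","wing","n_growing","P9",0
"raw","wing","n_growing","P10",1
"raw","wing","distal","S10/S11",3
"raw","wing","distal","S9/S10",2
"raw","wing","distal","S8/S9",1
"raw","wing","distal","S7/S8",0
"raw","wing","distal","S6/S7",1
"raw","wing","distal","S5/S6",0
"raw","wing","distal","S4/S5",0
"raw","wing","distal","S3/S4",1
"raw","wing","distal","S2/S3",1
"raw","wing","distal","S1/S2",0
"raw","wing","distal","P1/S1",0
"raw","wing","distal","P1/P2",5
"raw","wing","distal","P2/P3",10
"raw","wing","distal","P3/P4",7
"raw","wing","distal","P4/P5",9
"raw","wing","distal","P5/P6",15
"raw","wing","distal","P6/P7",13
"raw","wing","distal","P7/P8",9
"raw","wing","distal","P8/P9",4
"raw","wing","distal","P9/P10",1
"raw","wing","proximal","S10/S11",2
"raw","wing","proximal","S9/S10",1
"raw","wing","proximal","S8/S9",1
"raw","wing","proximal","S7/S8",1
"raw","wing","proximal","S6/S7",0
"raw","wing","proximal","S5/S6",1
"raw","wing","proximal","S4/S5",0
"raw","wing","proximal","S3/S4",0
"raw","wing","proximal","S2/S3",4
"raw","wing","proximal","S1/S2",6
"raw","wing","proximal","P1/S1",2
"raw","wing","proximal","P1/P2",0
"raw","wing","proximal","P2/P3",0
"raw","wing","proximal","P3/P4",0
"raw","wing","proximal","P4/P5",0
"raw","wing","proximal","P5/P6",0
"raw","wing","proximal","P6/P7",0
"raw","wing","proximal","P7/P8",0
"raw","wing","proximal","P8/P9",0
"raw","wing","proximal","P9/P10",0
"raw","wing","ambiguous","S10/S11",0
"raw","wing","ambiguous","S9/S10",1
"raw","wing","ambiguous","S8/S9",0
"raw","wing","ambiguous","S7/S8",0
"raw","wing","ambiguous","S6/S7",0
"raw","wing","ambiguous","S5/S6",0
"raw","wing","ambiguous","S4/S5",0
"raw","wing","ambiguous","S3/S4",0
"raw","wing","ambiguous","S2/S3",0
"raw","wing","ambiguous","S1/S2",0
"raw","wing","ambiguous","P1/S1",0
"raw","wing","ambiguous","P1/P2",0
"raw","wing","ambiguous","P2/P3",0
"raw","wing","ambiguous","P3/P4",0
"raw","wing","ambiguous","P4/P5",0
"raw","wing","ambiguous","P5/P6",0
"raw","wing","ambiguous","P6/P7",0
"raw","wing","ambiguous","P7/P8",0
"raw","wing","ambiguous","P8/P9",0
"raw","wing","ambiguous","P9/P10",0
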