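"specimen_id","sex","primary_rate","rectrix_rate"
"USNM 377660","M",2,2.5
"USNM 405410","M",3,2.5
"USNM 377661","M",3.5,3
"BM 1923.9.1580","M",3.5,2.5
"FMNH 153450","M",2.5,2.5
"FMNH 87584","M",2.5,2
"MCZ 167287","M",3,2.5
"MCZ 290664","M",3,2
"BM 1903.12.2.44","F",2.5,2.5
"BM 1939.12.9.1681","F",3,2.5
"MVZ 89582","F",2.5,2.5
"Yale 74979","F",3.5,2.5
"FMNH 153451","F",2.5,1.5
"FMNH 87586","F",3,1.5
"FMNH 87583","F",2.5,2
"FMNH 302623","F",3,2.5
"FMNH 302625","F",3.5,2
"MCZ 167286","F",2.5,1.5
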