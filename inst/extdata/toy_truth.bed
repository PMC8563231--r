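1	93951	460745	S01
1	506450	606450	S01
1	1125980	1225980	S01
1	1235557	1418763	S01
2	32581	159105	S01
2	617572	991048	S01
1	105876	480876	S02
2	302080	452080	S02
2	726948	826948	S02
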