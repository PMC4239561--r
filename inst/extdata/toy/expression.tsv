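gene_id	leaf	root
s01A1	10	30
s01B1	5	2
s02A1	0	4
s03A1	7	7
s03B1	2	2
s04A1	1	0
s05A1	2	8
s06A1	0	0
s07B2	3	9
s08A1	12	6
s09A1	6	1
s10A1	4	4
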