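set_id	spA	spB	spC
s01	s01A1,s01A2	s01B1,s01B2	s01C1,s01C2
s02	s02A1,s02A2	s02B1,s02B2	s02C1
s03	s03A1,s03A2	s03B1	s03C1
s04	s04A1	s04B1	s04C1
s05	s05A1	s05B1
s06	s06A1,s06A2	s06B1,s06B2	s06C1
s07	s07A1	s07B1,s07B2	s07C1
s08	s08A1	s08B1	s08C1
s09	s09A1,s09A2	s09B1	s09C1
s10	s10A1	s10B1	s10C1,s10C2
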