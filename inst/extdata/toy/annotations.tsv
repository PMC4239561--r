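s01A1	GO:0006979
s02B1	GO:0044237
s03A1	GO:0006979
s03A2	GO:0003824
s04A1	GO:0044237
s05A1	GO:0006979
s06A1	GO:0044237
s07B2	GO:0050896
s08A1	GO:0003824
s10A1	GO:0006979
s10A1	GO:0044237
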