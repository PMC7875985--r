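chr1	1000	1450	peak_0001
chr1	5200	5480	peak_0002
chr1	9100	9400	peak_0003
chr2	800	1100	peak_0004
chr2	4300	4620	peak_0005
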