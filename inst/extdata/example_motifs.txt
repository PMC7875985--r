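>Ebox_CAGCTG
0.02 0.94 0.02 0.02
0.94 0.02 0.02 0.02
0.02 0.02 0.94 0.02
0.02 0.94 0.02 0.02
0.02 0.02 0.02 0.94
0.02 0.02 0.94 0.02
>GCbox
0.05 0.05 0.85 0.05
0.05 0.05 0.85 0.05
0.05 0.05 0.85 0.05
0.05 0.85 0.05 0.05
0.05 0.05 0.85 0.05
0.05 0.05 0.85 0.05
0.05 0.05 0.85 0.05
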