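difficulty
-1.33
-0.9
-0.6
-0.34
-0.11
0.12
0.36
0.61
0.92
1.34
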