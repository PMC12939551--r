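value
10
14
20
23
24
25
26
29
44
44
49
56
59
60
61
62
70
76
79
84
90
101
118
130
156
186
208
208
310
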