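value
7
47
58
74
177
232
273
285
317
429
440
445
455
468
495
497
532
571
579
581
650
702
715
779
881
900
930
968
1077
1109
1314
1334
1367
1534
1712
1784
1877
1886
2045
2056
2260
2429
250
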