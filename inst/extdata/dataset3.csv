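value
10.49
8.8
12.42
4.58
6.85
4.58
5.0
4.75
4.75
12.25
9.5
13.54
10.42
4.65
9.88
6.21
8.6
7.06
7.96
7.89
9.7
13.9
12.65
10.0
12.65
12.07
9.8
13.54
9.82
13.54
12.42
12.73
12.22
12.25
12.32
8.75
12.0
17.5
11.88
13.13
13.56
15.44
13.22
7.28
11.7
11.7
11.6
10.9
11.84
8.0
10.2
5.77
13.9
4.58
12.07
15.44
10.2
11.0
8.5
10.99
10.39
9.9
13.94
15.21
13.56
9.0
20.47
15.22
11.5
13.9
13.22
10.48
15.48
9.8
12.21
13.56
7.04
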