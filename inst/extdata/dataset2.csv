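value
12
17
7
13
5
2
12
2
6
4
5
14
6
2
4
18
4
19
5
14
20
8
11
26
1
3
10
18
6
10
23
7
20
4
7
6
12
10
20
3
12
3
18
18
14
14
8
6
22
11
8
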