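# SWC written by cpmorph (coordinates in micrometres)
1 0 0 0 10 1 -1
2 0 0 0 9 1 1
3 0 0 0 8 1 2
4 0 0 0 7 1 3
5 0 0 0 6 1 4
6 0 0 0 5 1 5
7 0 0 0 4 1 6
8 0 0 0 3 1 7
9 0 0 0 2 1 8
10 0 0 0 1 1 9
11 0 0 0 0 1 10
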