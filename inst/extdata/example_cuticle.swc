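# SWC written by cpmorph (coordinates in micrometres)
1 0 0.2 0 1.8 1 -1
2 0 0.2 0 3.098 1 1
3 0 0.2 0 4.396 1 2
4 0 0.2 0 5.694 1 3
5 0 0.2 0 6.992 1 4
6 0 0.2 0 8.29 1 5
7 0 0.2 0 9.588 1 6
8 0 0.2 0 10.886 1 7
9 0 0.2 0 12.184 1 8
10 0 0.2 0 13.482 1 9
11 0 0.2 0 14.78 1 10
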