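%%MatrixMarket matrix coordinate integer general
12 8 69
1 1 3
2 1 1
3 1 5
4 1 1
5 1 3
6 1 4
7 1 7
8 1 5
10 1 4
11 1 2
1 2 1
2 2 2
3 2 6
4 2 4
5 2 1
6 2 2
7 2 3
8 2 7
10 2 3
1 3 3
2 3 6
3 3 1
5 3 2
6 3 2
7 3 4
9 3 1
11 3 1
12 3 2
1 4 1
2 4 1
3 4 3
6 4 2
7 4 1
10 4 2
1 5 3
2 5 4
4 5 2
5 5 3
6 5 1
7 5 2
8 5 8
9 5 4
10 5 4
12 5 7
2 6 1
3 6 2
4 6 5
5 6 2
6 6 1
7 6 2
9 6 2
10 6 3
11 6 1
12 6 3
3 7 6
4 7 2
5 7 8
7 7 1
8 7 5
10 7 6
11 7 4
12 7 4
1 8 10
2 8 2
4 8 8
9 8 45
10 8 1
11 8 11
12 8 5
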