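# SYNTHETIC calibrant anchor table: allele ladders anchored at
# plausible fragment sizes (flank + 4*repeats + microvariant +
# per-marker mobility offset).  Real anchor sizes are
# instrument specific and are supplied by the user.
marker,allele,size_bp
18-3,16,134.12
18-3,19,146.12
18-3,21,154.12
4-2,16,214.31
4-2,16.3,217.31
4-2,19.3,229.31
4-2,20.3,233.31
11-1,19,306.47
11-1,19.3,309.47
11-1,20.3,313.47
6-7,12,368.22
6-7,15,380.22
6-7,16,384.22
19-2,12,478.58
19-2,13,482.58
19-2,14,486.58
1-2,13,182.17
1-2,15,190.17
1-2,18,202.17
7-1,26.2,366.63
7-1,28,372.63
7-1,29,376.63
1-1,11,444.28
1-1,14,456.28
3-2,13.1,533.52
3-2,14,536.52
8-1,14,96.41
8-1,15,100.41
8-1,16,104.41
2-1,9,96.44
15-3,18,212.19
15-3,20.3,223.19
15-3,22.3,231.19
15-3,23.3,235.19
6-4,15.3,343.56
6-4,18,352.56
6-4,18.3,355.56
11-2,15,440.33
11-2,15.3,443.33
11-2,18,452.33
17-2,15,120.49
17-2,16,124.49
12-1,15,220.15
12-1,16,224.15
12-1,18,232.15
5-5,13,322.38
5-5,16,334.38
5-5,17,338.38
X-1,24,466.61
X-1,25,470.61
X-1,28,482.61
13-1,16.2,586.24
13-1,17,588.24
13-1,17.1,589.24
13-1,18,592.24
D8S1106,10,45.35
D8S1106,12,53.35
D4S2408,10,50.27
D4S2408,12,58.27
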