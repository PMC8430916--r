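slot,family,phase
1,non-polar,Squalane
2,non-polar,DB-1
3,non-polar,DB-5
4,non-polar,OV-1
5,non-polar,OV-101
6,non-polar,SE-30
7,non-polar,SE-52
8,non-polar,SE-54
9,non-polar,HP-1
10,non-polar,HP-5
11,non-polar,DB-5MS
12,non-polar,Apiezon L
13,non-polar,Apiezon M
14,non-polar,CP-Sil 5 CB
15,non-polar,CP-Sil 8 CB
16,non-polar,OV-73
17,non-polar,SPB-1
18,non-polar,SPB-5
19,non-polar,Rtx-1
20,non-polar,Rtx-5
21,non-polar,BP-1
22,non-polar,BP-5
23,non-polar,Ultra-1
24,non-polar,Ultra-2
25,non-polar,Methyl silicone
26,non-polar,5 % phenyl methyl siloxane
27,non-polar,SF-96
28,non-polar,OV-3
29,non-polar,OV-7
30,non-polar,DC-200
31,non-polar,Petrocol DH
32,non-polar,ZB-1
33,non-polar,ZB-5
34,non-polar,NB-30
35,non-polar,PONA
36,non-polar,Polydimethyl siloxane
1,polar,DB-WAX
2,polar,Carbowax 20M
3,polar,HP-Innowax
4,polar,Supelcowax-10
5,polar,FFAP
6,polar,DB-FFAP
7,polar,CP-Wax 52CB
8,polar,BP-20
9,polar,AT-Wax
10,polar,Rtx-Wax
11,polar,Stabilwax
12,polar,HP-20M
13,polar,PEG-20M
14,polar,PEG-4000
15,polar,TC-WAX
16,polar,ZB-WAX
17,polar,Innowax FSC
18,polar,OV-351
19,polar,SP-1000
20,polar,Carbowax 1540
21,polar,Other polar
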