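age,qx
40,2e-04
41,0.00021774
42,0.00023706
43,0.00025809
44,0.00028099
45,0.00030592
46,0.00033306
47,0.00036261
48,0.00039478
49,0.0004298
50,0.00046793
51,0.00050944
52,0.00055464
53,0.00060384
54,0.00065742
55,0.00071574
56,0.00077924
57,0.00084837
58,0.00092364
59,0.00100558
60,0.00109479
61,0.00119192
62,0.00129766
63,0.00141278
64,0.00153812
65,0.00167458
66,0.00182314
67,0.00198489
68,0.00216098
69,0.0023527
70,0.00256142
71,0.00278866
72,0.00303606
73,0.00330542
74,0.00359866
75,0.00391792
76,0.00426551
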