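"age","qx"
50,0.00202612449840511
51,0.00220004168648291
52,0.00239375804733311
53,0.00260952303556061
54,0.00284984058168281
55,0.00311749761687818
56,0.00341559573141581
57,0.0037475862955243
58,0.00411730940212429
59,0.00452903702338536
60,0.00498752080731768
61,0.00549804497629358
62,0.00606648482610439
63,0.00669937136129983
64,0.00740396263931686
65,0.00818832243116996
66,0.0090614068387771
67,0.0100331595364097
68,0.0111146163237847
69,0.0123180196877747
70,0.013656944064532
71,0.0151464324689023
72,0.0168031451069317
73,0.0186455205020968
74,0.0206939495367917
75,0.0229709626255231
76,0.0255014299805317
77,0.0283127745864009
78,0.0314351970463465
79,0.0349019108739411
80,0.0387493860502001
81,0.043017597712494
82,0.0477502756488172
83,0.0529951487935691
84,0.0588041771095968
85,0.0652337610426446
86,0.0723449160939136
87,0.0802033969213899
88,0.088879751705379
89,0.0984492832676763
90,0.108991888612491
91,0.120591743197606
92,0.1333367904455
93,0.147317990954857
94,0.162628279885264
95,0.17936117554044
96,0.197608977961912
97,0.217460494330678
98,0.238998229450787
99,0.262294986223454
100,0.28740983488367
101,0.314383433321294
102,0.343232716802069
103,0.373945026692698
104,0.406471816955526
105,0.440722165922144
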