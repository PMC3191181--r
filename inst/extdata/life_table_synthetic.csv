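age,qx
50,0.00316291516984946
51,0.0034573053778737
52,0.0037841857953661
53,0.00414712966047337
54,0.00455010026684821
55,0.00499749285804318
56,0.00549418086096198
57,0.00604556686962798
58,0.00665763882018777
59,0.00733703182741618
60,0.00809109618116777
61,0.00892797202714057
62,0.00985667127853307
63,0.0108871673218391
64,0.012030493088783
65,0.0132988480642753
66,0.0147057147835388
67,0.0162659853355797
68,0.0179960983291994
69,0.019914186684728
70,0.0220402364809484
71,0.0243962569018333
72,0.0270064610790861
73,0.02989745729896
74,0.0330984496174791
75,0.0366414463858731
76,0.0405614745031679
77,0.0448967963571378
78,0.0496891253561236
79,0.0549838346568253
80,0.0608301521182629
81,0.0672813326187583
82,0.0743947966199527
83,0.0822322212111094
84,0.0908595667869555
85,0.100347018985114
86,0.110768821539052
87,0.122202971327904
88,0.134730742214178
89,0.148435999413502
90,0.163404261393027
91,0.179721462030119
92,0.197472362527768
93,0.216738561128436
94,0.237596049987991
95,0.260112273938115
96,0.284342656847625
97,0.310326579744566
98,0.338082822859197
99,0.367604523452852
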