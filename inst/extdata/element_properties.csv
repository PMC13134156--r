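z,symbol,atomic_weight,group,period,block,valence_electrons,covalent_radius,vdw_radius,en_pauling,en_allen,electron_affinity,ionization_energy,melting_point,boiling_point,density,atomic_volume
1,H,1.008,1,1,0,1,0.31,1.2,2.2,2.3,0.754,13.598,13.99,20.27,8.99e-05,11212.458
2,He,4.003,18,1,0,2,0.28,1.4,,4.16,,24.587,0.95,4.22,0.0001785,22425.77
3,Li,6.941,1,2,0,1,1.28,2.2,0.98,0.912,0.618,5.392,453.7,1560,0.534,12.998
4,Be,9.012,2,2,0,2,0.96,1.9,1.57,1.576,,9.323,1560,2742,1.85,4.871
5,B,10.812,13,2,1,3,0.84,1.8,2.04,2.051,0.28,8.298,2349,4200,2.34,4.621
6,C,12.011,14,2,1,4,0.76,1.7,2.55,2.544,1.263,11.26,3823,4300,2.267,5.298
7,N,14.007,15,2,1,5,0.71,1.6,3.04,3.066,-0.07,14.534,63.15,77.36,0.001251,11196.643
8,O,15.999,16,2,1,6,0.66,1.55,3.44,3.61,1.461,13.618,54.36,90.2,0.001429,11195.941
9,F,18.998,17,2,1,7,0.57,1.5,3.98,4.193,3.401,17.423,53.5,85.0,0.001696,11201.651
10,Ne,20.18,18,2,1,8,0.58,1.54,,4.787,,21.565,24.56,27.1,0.0009,22422.222
11,Na,22.99,1,3,0,1,1.66,2.4,0.93,0.869,0.548,5.139,370.9,1156,0.971,23.677
12,Mg,24.305,2,3,0,2,1.41,2.2,1.31,1.293,,7.646,923,1363,1.738,13.984
13,Al,26.982,13,3,1,3,1.21,2.1,1.61,1.613,0.433,5.986,933.5,2792,2.698,10.001
14,Si,28.086,14,3,1,4,1.11,2.1,1.9,1.916,1.39,8.152,1687,3538,2.329,12.059
15,P,30.974,15,3,1,5,1.07,1.95,2.19,2.253,0.746,10.487,317.3,553.7,1.82,17.019
16,S,32.067,16,3,1,6,1.05,1.8,2.58,2.589,2.077,10.36,388.4,717.8,2.067,15.514
17,Cl,35.453,17,3,1,7,1.02,1.8,3.16,2.869,3.613,12.968,171.6,239.1,0.003214,11030.803
18,Ar,39.948,18,3,1,8,1.06,1.88,,3.242,,15.76,83.8,87.3,0.001784,22392.377
19,K,39.098,1,4,0,1,2.03,2.8,0.82,0.734,0.501,4.341,336.5,1032,0.862,45.357
20,Ca,40.078,2,4,0,2,1.76,2.4,1.0,1.034,0.025,6.113,1115,1757,1.54,26.025
21,Sc,44.956,3,4,2,3,1.7,2.3,1.36,1.19,0.188,6.561,1814,3109,2.989,15.04
22,Ti,47.867,4,4,2,4,1.6,2.15,1.54,1.38,0.079,6.828,1941,3560,4.506,10.623
23,V,50.944,5,4,2,5,1.52,2.05,1.63,1.53,0.525,6.746,2183,3680,6.0,8.491
24,Cr,51.996,6,4,2,6,1.39,2.05,1.66,1.65,0.666,6.767,2180,2944,7.19,7.232
25,Mn,54.938,7,4,2,7,1.39,2.05,1.55,1.75,,7.434,1519,2334,7.21,7.62
26,Fe,55.845,8,4,2,8,1.32,2.05,1.83,1.8,0.151,7.902,1811,3134,7.874,7.092
27,Co,58.933,9,4,2,9,1.26,2.0,1.88,1.84,0.662,7.881,1768,3200,8.9,6.622
28,Ni,58.693,10,4,2,10,1.24,2.0,1.91,1.88,1.156,7.64,1728,3186,8.908,6.589
29,Cu,63.546,11,4,2,11,1.32,2.0,1.9,1.85,1.235,7.726,1357.8,2835,8.96,7.092
30,Zn,65.39,12,4,2,2,1.22,2.1,1.65,1.59,,9.394,692.7,1180,7.14,9.158
31,Ga,69.723,13,4,1,3,1.22,2.1,1.81,1.756,0.43,5.999,302.9,2477,5.91,11.797
32,Ge,72.61,14,4,1,4,1.2,2.1,2.01,1.994,1.233,7.899,1211.4,3106,5.323,13.641
33,As,74.922,15,4,1,5,1.19,2.05,2.18,2.211,0.804,9.789,1090,887,5.776,12.971
34,Se,78.96,16,4,1,6,1.2,1.9,2.55,2.424,2.021,9.752,494,958,4.809,16.419
35,Br,79.904,17,4,1,7,1.2,1.9,2.96,2.685,3.364,11.814,265.8,332,3.122,25.594
36,Kr,83.8,18,4,1,8,1.16,2.02,3.0,2.966,,14.0,115.8,119.9,0.003749,22352.627
37,Rb,85.468,1,5,0,1,2.2,2.9,0.82,0.706,0.486,4.177,312.5,961,1.532,55.789
38,Sr,87.62,2,5,0,2,1.95,2.55,0.95,0.963,0.048,5.695,1050,1655,2.64,33.189
39,Y,88.906,3,5,2,3,1.9,2.4,1.22,,0.307,6.217,1799,3609,4.469,19.894
40,Zr,91.224,4,5,2,4,1.75,2.3,1.33,,0.426,6.634,2128,4682,6.506,14.022
41,Nb,92.906,5,5,2,5,1.64,2.15,1.6,,0.893,6.759,2750,5017,8.57,10.841
42,Mo,95.94,6,5,2,6,1.54,2.1,2.16,,0.748,7.092,2896,4912,10.22,9.387
43,Tc,98.0,7,5,2,7,1.47,2.05,1.9,,0.55,7.28,2430,4538,11.5,8.522
44,Ru,101.07,8,5,2,8,1.46,2.05,2.2,,1.05,7.361,2607,4423,12.37,8.171
45,Rh,102.906,9,5,2,9,1.42,2.0,2.28,,1.137,7.459,2237,3968,12.41,8.292
46,Pd,106.42,10,5,2,10,1.39,2.05,2.2,,0.562,8.337,1828,3236,12.02,8.854
47,Ag,107.868,11,5,2,11,1.45,2.1,1.93,,1.302,7.576,1234.9,2435,10.49,10.283
48,Cd,112.412,12,5,2,2,1.44,2.2,1.69,,,8.994,594.2,1040,8.65,12.996
49,In,114.818,13,5,1,3,1.42,2.2,1.78,1.656,0.3,5.786,429.8,2345,7.31,15.707
50,Sn,118.711,14,5,1,4,1.39,2.25,1.96,1.824,1.112,7.344,505.1,2875,7.287,16.291
51,Sb,121.76,15,5,1,5,1.39,2.2,2.05,1.984,1.046,8.608,903.8,1860,6.685,18.214
52,Te,127.6,16,5,1,6,1.38,2.1,2.1,2.158,1.971,9.01,722.7,1261,6.232,20.475
53,I,126.904,17,5,1,7,1.39,2.1,2.66,2.359,3.059,10.451,386.9,457.6,4.93,25.741
54,Xe,131.29,18,5,1,8,1.4,2.16,2.6,2.582,,12.13,161.4,165.1,0.005894,22275.195
55,Cs,132.905,1,6,0,1,2.44,3.0,0.79,0.659,0.472,3.894,301.6,944,1.873,70.958
56,Ba,137.328,2,6,0,2,2.15,2.7,0.89,0.881,0.145,5.212,1000,2170,3.594,38.21
57,La,138.906,,6,3,3,2.07,2.5,1.1,,0.47,5.577,1193,3737,6.145,22.605
58,Ce,140.116,,6,3,4,2.04,2.48,1.12,,0.65,5.539,1068,3716,6.77,20.697
59,Pr,140.908,,6,3,3,2.03,2.47,1.13,,,5.473,1208,3793,6.773,20.804
60,Nd,144.24,,6,3,4,2.01,2.45,1.14,,,5.525,1297,3347,7.007,20.585
61,Pm,145.0,,6,3,5,1.99,2.43,,,,5.582,1315,3273,7.26,19.972
62,Sm,150.36,,6,3,6,1.98,2.42,1.17,,,5.644,1345,2067,7.52,19.995
63,Eu,151.964,,6,3,7,1.98,2.4,,,,5.67,1099,1802,5.243,28.984
64,Gd,157.25,,6,3,8,1.96,2.38,1.2,,,6.15,1585,3546,7.895,19.918
65,Tb,158.925,,6,3,9,1.94,2.37,1.1,,,5.864,1629,3503,8.229,19.313
66,Dy,162.5,,6,3,10,1.92,2.35,1.22,,,5.939,1680,2840,8.55,19.006
67,Ho,164.93,,6,3,11,1.92,2.33,1.23,,,6.022,1734,2993,8.795,18.753
68,Er,167.26,,6,3,12,1.89,2.32,1.24,,,6.108,1802,3141,9.066,18.449
69,Tm,168.934,,6,3,13,1.9,2.3,1.25,,,6.184,1818,2223,9.321,18.124
70,Yb,173.04,,6,3,14,1.87,2.28,,,,6.254,1097,1469,6.965,24.844
71,Lu,174.967,,6,3,15,1.87,2.27,1.27,,,5.426,1925,3675,9.84,17.781
72,Hf,178.49,4,6,2,4,1.75,2.25,1.3,,0.017,6.825,2506,4876,13.31,13.41
73,Ta,180.948,5,6,2,5,1.7,2.2,1.5,,0.322,7.55,3290,5731,16.69,10.842
74,W,183.84,6,6,2,6,1.62,2.1,2.36,,0.815,7.864,3695,5828,19.25,9.55
75,Re,186.207,7,6,2,7,1.51,2.05,1.9,,0.15,7.834,3459,5869,21.02,8.859
76,Os,190.23,8,6,2,8,1.44,2.0,2.2,,1.1,8.438,3306,5285,22.59,8.421
77,Ir,192.217,9,6,2,9,1.41,2.0,2.2,,1.565,8.967,2719,4701,22.56,8.52
78,Pt,195.078,10,6,2,10,1.36,2.05,2.28,,2.128,8.959,2041.4,4098,21.45,9.095
79,Au,196.967,11,6,2,11,1.36,2.1,2.54,,2.309,9.226,1337.3,3129,19.3,10.206
80,Hg,200.59,12,6,2,2,1.32,2.05,2.0,,,10.437,234.3,629.9,13.534,14.821
81,Tl,204.383,13,6,1,3,1.45,2.2,1.62,1.789,0.377,6.108,577,1746,11.85,17.248
82,Pb,207.2,14,6,1,4,1.46,2.3,2.33,1.854,0.356,7.417,600.6,2022,11.34,18.272
83,Bi,208.98,15,6,1,5,1.48,2.3,2.02,2.01,0.942,7.286,544.6,1837,9.78,21.368
84,Po,209.0,16,6,1,6,1.4,2.0,2.0,2.19,1.9,8.414,527,1235,9.196,22.727
85,At,210.0,17,6,1,7,1.5,2.0,2.2,2.39,2.8,9.318,575,610,,
86,Rn,222.0,18,6,1,8,1.5,2.0,2.2,2.6,,10.748,202,211.5,0.00973,22816.033
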