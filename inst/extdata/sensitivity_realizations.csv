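realization,Vmax_IP3R,V_LEAK,Vmax_SERCA,Vmax_UNI,Vmax_NCX,k_Hyd,rho_f1,rho_res,Vmax_ANT,g_H,Vmax_CS,kf_ACO,Vmax_IDH,Vmax_KGDH,kf_SL,Vmax_SDH,kf_FH,Vmax_MDH
000,32.2596,0.1642,0.1240,0.2873,0.0022,0.0965,0.2184,1.0192,4.2549,1.0619E-05,108.3939,11.5072,1.7347,2.4632,0.1172,0.5253,8.0114,116.2057
001,28.9361,0.1534,0.1096,0.2848,0.0021,0.0927,0.2245,0.9483,3.6600,9.3595E-06,99.4006,11.7411,1.6571,2.6330,0.1256,0.5206,8.5725,135.9840
002,30.5150,0.1605,0.1318,0.3071,0.0019,0.0979,0.2482,1.0536,4.0513,1.0947E-05,102.4775,12.6271,1.7147,2.3530,0.1154,0.4575,8.5594,122.5774
003,31.0669,0.1554,0.1253,0.2772,0.0022,0.0930,0.2503,0.9669,4.0765,9.9902E-06,110.9615,11.7229,1.6930,2.4687,0.1197,0.4912,8.0044,139.9750
004,28.7386,0.1455,0.1189,0.2864,0.0020,0.0825,0.2092,0.9833,4.0047,1.0317E-05,101.1696,11.6808,1.6536,2.5032,0.1282,0.4659,8.7464,116.1729
005,28.1559,0.1444,0.1203,0.3194,0.0021,0.0897,0.2305,1.0486,4.0864,9.2162E-06,98.4237,11.2521,1.8507,2.7108,0.1354,0.4726,8.1926,139.9104
006,29.6631,0.1564,0.1305,0.2858,0.0021,0.0873,0.2454,0.9942,4.2314,1.0591E-05,110.0077,12.7928,1.7842,2.4806,0.1351,0.4681,8.2690,126.8040
007,30.5407,0.1521,0.1207,0.2950,0.0021,0.0990,0.2472,1.0667,4.2996,1.0043E-05,98.4102,13.6152,1.7793,2.4885,0.1318,0.4539,7.5623,122.7604
008,28.8359,0.1482,0.1111,0.2974,0.0021,0.0955,0.2267,0.9762,4.3768,1.0999E-05,105.9501,11.6257,1.6276,2.3945,0.1283,0.4530,7.9402,137.5818
009,28.9146,0.1610,0.1169,0.2757,0.0019,0.0831,0.2509,1.0335,3.7614,1.0627E-05,103.0207,13.2424,1.8459,2.3296,0.1385,0.4759,8.6330,126.7602
ref,30.0000,0.1500,0.1200,0.3000,0.0020,0.0900,0.2300,1.0000,4.0000,1.000E-05,104.0000,12.5000,1.7767,2.5000,0.1250,0.5000,8.3000,128.0000
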