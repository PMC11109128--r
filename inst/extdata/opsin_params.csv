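name,Gd1,Gd2,Gr,phi_m,k1,k2,kf,kb,Gf0,Gb0,p,q,gamma,E_opsin,g_opsin,A1,A2,A3,B1,B2,B3,sigma1,sigma2,sigma3
ChRmine,0.02,0.0133,0.00059,2.1e+15,0.2,0.004,0.001,0,0.003,0.005,0.8,1,0.05,5.64,41.14,0.973,0.0973,0,515,450,0,42,40,0
rsChRmine,0.00625,0.00435,0.00059,5e+17,4.1,0.1,0.01,0,0.0032,0.006,0.8,0.1,0.05,5.64,35.14,1.058,-0.423,0,510,465,0,50,25,0
hsChRmine,0.04,0.02,0.00059,4e+15,0.22,4e-05,0.001,0,0.0042,0.005,0.8,1,0.05,5.64,53.54,1,0.1,0,515,390,0,44,40,0
frChRmine,0.0167,0.00833,0.00059,1e+15,0.2,0.004,0.001,0,0.003,0.005,0.8,1,0.05,5.64,11.28,0.958,0.134,0,585,545,0,16,25,0
ReaChR,0.0077,0.00125,3.3e-05,5e+17,1.2,0.01,0.012,0.001,5e-04,5e-04,1,1,0.05,7,8.15,0.917,0.138,0,590,510,0,16,80,0
bReaChES,0.025,0.01,3.3e-05,6e+15,0.4,0.01,0.01,0.04,0.002,0.002,1,1,0.05,10,38.48,0.566,0.828,0.349,575,480,550,15,52,30
CoChR,0.00893,0.00667,5e-04,4e+15,0.15,0.01,0.008,0.012,0.002,5e-04,0.98,0.98,0.05,25,25.47,0.894,0.304,0,480,420,0,30,40,0
CoChR-LC,0.00286,0.000833,5e-04,3.8e+15,0.15,0.01,0.003,0.01,5e-04,0.001,0.98,0.98,0.05,25,21.87,0.976,0.156,0,478,420,0,30,40,0
CoChR-3M,0.00118,0.000692,5e-04,3.5e+15,0.15,0.01,0.001,0.01,5e-04,1e-04,0.98,0.98,0.05,25,21.65,0.922,0.203,0,476,420,0,28,40,0
CatCh,0.0625,0.01,2e-04,1.5e+17,3,0.1,0.03,0.06,0.02,0.039,1,1,0.05,-20,63,1.245,-0.5,0,478,509,0,40,31,0
PsCatCh2.0,0.05,0.004,5e-04,3.5e+16,7,8,1,0.1,0.001,3e-04,1.2,1.2,0.2,12.5,43.95,1.086,-0.33,0,442,470,0,40,20,0
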