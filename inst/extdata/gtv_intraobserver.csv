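observer,patient,scheme,mean_cm3,sd_cm3,cov
1,1,dual,21.52,1.48,0.07
1,2,dual,14.05,0.34,0.02
1,3,dual,2.64,0.29,0.11
2,1,dual,22.52,1.00,0.04
2,2,dual,16.46,0.51,0.03
2,3,dual,2.79,0.12,0.04
3,1,dual,20.28,0.96,0.05
3,2,dual,14.63,0.60,0.04
3,3,dual,1.99,0.16,0.08
1,1,tri,17.15,0.68,0.04
1,2,tri,12.44,0.16,0.01
1,3,tri,1.87,0.02,0.01
2,1,tri,19.76,0.31,0.02
2,2,tri,14.08,0.13,0.01
2,3,tri,1.94,0.02,0.01
3,1,tri,17.55,0.47,0.03
3,2,tri,13.40,0.17,0.01
3,3,tri,1.66,0.02,0.01
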