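patient,scheme,observer,adsc_cm
1,dual,1,1.77
1,dual,2,1.86
1,dual,3,1.79
2,dual,1,1.58
2,dual,2,1.67
2,dual,3,1.58
3,dual,1,0.95
3,dual,2,0.97
3,dual,3,0.85
1,tri,1,1.73
1,tri,2,1.77
1,tri,3,1.72
2,tri,1,1.51
2,tri,2,1.56
2,tri,3,1.53
3,tri,1,0.83
3,tri,2,0.84
3,tri,3,0.82
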