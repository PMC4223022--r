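patient,scheme,observer,volume_cm3
1,dual,1,19.91
1,dual,2,22.72
1,dual,3,20.47
2,dual,1,14.39
2,dual,2,17.01
2,dual,3,13.94
3,dual,1,2.96
3,dual,2,2.92
3,dual,3,1.82
1,tri,1,17.91
1,tri,2,19.82
1,tri,3,17.69
2,tri,1,12.61
2,tri,2,14.09
2,tri,3,13.27
3,tri,1,1.89
3,tri,2,1.92
3,tri,3,1.64
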