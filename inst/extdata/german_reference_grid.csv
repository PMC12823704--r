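threshold_pct,start_age,share_pct,mean_risk_pct
7.5,25,23.20,11.72
7.5,40,22.98,17.57
7.5,50,21.97,16.22
7.5,60,16.36,18.00
7.5,70,7.10,29.30
10,25,19.16,13.53
10,40,19.02,22.56
10,50,18.41,21.82
10,60,14.59,21.23
10,70,6.71,30.60
15,25,13.85,16.60
15,40,13.77,29.31
15,50,13.50,30.08
15,60,11.50,28.68
15,70,5.94,34.20
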