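form,compound,phase,nu_i,dG_TS_R,dG_TS_P,k_fwd_printed,k_rev_printed
D1p,2AP,gas,1702.2,21.684,28.246,0.0733,1.13e-06
D1p,2AP,heptane,1702.2,20.512,26.957,0.53,1e-05
D1p,2AP,water,1702.2,19.152,26.707,5.26,1.52e-05
D2p,2AP,gas,1426.7,15.754,9.478,1270,50700000
D2p,2AP,heptane,1426.7,15.27,9.095,2880,96800000
D2p,2AP,water,1426.7,13.26,7.645,85700,1.12e+09
D5p,2AP,gas,2297.8,33.439,21.308,2.85e-10,0.222
D5p,2AP,heptane,2297.8,32.729,21.308,9.43e-10,0.222
D5p,2AP,water,2297.8,30.819,22.218,2.37e-08,0.0478
D1p,L3HOK,gas,1841.9,26.384,28.168,2.96e-05,1.46e-06
D1p,L3HOK,heptane,1841.9,25.808,27.555,7.83e-05,4.1e-06
D1p,L3HOK,water,1841.9,23.568,27.695,0.00343,3.24e-06
D2p,L3HOK,gas,1385.9,15.373,16.224,2330,554
D2p,L3HOK,heptane,1385.9,14.325,17.961,13700,29.5
D2p,L3HOK,water,1385.9,13.665,15.141,41600,3450
D5p,L3HOK,gas,2089.6,34.355,21.234,5.19e-11,0.216
D5p,L3HOK,heptane,2089.6,32.479,20.242,1.23e-09,1.15
D5p,L3HOK,water,2089.6,31.459,20.112,6.88e-09,1.43
D1p,3HAA,gas,1883.6,27.034,29.501,1.02e-05,1.59e-07
D1p,3HAA,heptane,1883.6,26.164,28.827,4.44e-05,4.96e-07
D1p,3HAA,water,1883.6,24.764,28.937,0.000472,4.12e-07
D2p,3HAA,gas,1424.2,15.283,8.012,2810,6.01e+08
D2p,3HAA,heptane,1424.2,14.452,8.24,11400,4.09e+08
D2p,3HAA,water,1424.2,13.272,7.89,83700,7.38e+08
D5p,3HAA,gas,2071.5,33.305,19.13,3.01e-10,7.41
D5p,3HAA,heptane,2071.5,32.785,19.092,7.24e-10,7.89
D5p,3HAA,water,2071.5,31.235,20.242,9.9e-09,1.13
D1p,3HAAi,gas,1706.1,20.483,35.363,0.559,6.91e-12
D1p,3HAAi,heptane,1706.1,20.682,33.797,0.399,9.71e-11
D1p,3HAAi,water,1706.1,19.932,30.887,1.42,1.32e-08
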