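stage,compound,phase,dG
N1,2AP,gas,58.23
N1,L3HOK,gas,59.028
N1,3HAA,gas,58.689
N1,3HAAi,gas,48.361
N1,2AP,heptane,55.894
N1,L3HOK,heptane,57.757
N1,3HAA,heptane,57.31
N1,3HAAi,heptane,49.204
N1,2AP,water,55.914
N1,L3HOK,water,58.817
N1,3HAA,water,58.32
N1,3HAAi,water,54.274
N2,2AP,gas,64.4
N2,L3HOK,gas,67.063
N2,3HAA,gas,72.711
N2,3HAAi,gas,70.811
N2,2AP,heptane,67.302
N2,L3HOK,heptane,69.382
N2,3HAA,heptane,74.67
N2,3HAAi,heptane,72.947
N2,2AP,water,69.402
N2,L3HOK,water,70.022
N2,3HAA,water,74.51
N2,3HAAi,water,72.607
N3,2AP,gas,5.799
N3,L3HOK,gas,5.798
N3,3HAA,gas,3.095
N3,3HAAi,gas,37.676
N3,2AP,heptane,6.818
N3,L3HOK,heptane,8.351
N3,3HAA,heptane,6.019
N3,3HAAi,heptane,18.321
N3,2AP,water,7.108
N3,L3HOK,water,7.291
N3,3HAA,water,7.779
N3,3HAAi,water,-0.199
N4,2AP,gas,-12.182
N4,L3HOK,gas,-10.994
N4,3HAA,gas,-13.769
N4,3HAAi,gas,6.477
N4,2AP,heptane,-12.704
N4,L3HOK,heptane,-10.919
N4,3HAA,heptane,-15.538
N4,3HAAi,heptane,3.431
N4,2AP,water,-14.334
N4,L3HOK,water,-11.039
N4,3HAA,water,-16.938
N4,3HAAi,water,-4.039
N5,2AP,gas,53.284
N5,L3HOK,gas,53.127
N5,3HAA,gas,52.114
N5,3HAAi,gas,39.317
N5,2AP,heptane,50.953
N5,L3HOK,heptane,51.075
N5,3HAA,heptane,50.664
N5,3HAAi,heptane,40.584
N5,2AP,water,50.623
N5,L3HOK,water,51.315
N5,3HAA,water,51.294
N5,3HAAi,water,46.904
N6,2AP,gas,64.235
N6,L3HOK,gas,61.272
N6,3HAA,gas,70.485
N6,3HAAi,gas,64.68
N6,2AP,heptane,67.07
N6,L3HOK,heptane,63.903
N6,3HAA,heptane,72.002
N6,3HAAi,heptane,68.423
N6,2AP,water,69.25
N6,L3HOK,water,65.843
N6,3HAA,water,71.492
N6,3HAAi,water,72.493
N7,2AP,gas,-239.819
N7,L3HOK,gas,-230.274
N7,3HAA,gas,-241.921
N7,3HAAi,gas,-372.143
N7,2AP,water,-10.428
N7,L3HOK,water,-1.299
N7,3HAA,water,-9.277
N7,3HAAi,water,-17.979
N8,2AP,gas,230.936
N8,L3HOK,gas,222.443
N8,3HAA,gas,229.487
N8,3HAAi,gas,370.459
N8,2AP,water,3.197
N8,L3HOK,water,-5.319
N8,3HAA,water,1.788
N8,3HAAi,water,11.619
N9,2AP,gas,6.211
N9,L3HOK,gas,5.273
N9,3HAA,gas,12.539
N9,3HAAi,gas,36.516
N9,2AP,heptane,5.775
N9,L3HOK,heptane,3.509
N9,3HAA,heptane,10.986
N9,3HAAi,heptane,30.554
N9,2AP,water,5.485
N9,L3HOK,water,3.199
N9,3HAA,water,7.856
N9,3HAAi,water,16.334
N10,2AP,gas,-16.125
N10,L3HOK,gas,-19.18
N10,3HAA,gas,-28.209
N10,3HAAi,gas,-38.745
N10,2AP,heptane,-16.032
N10,L3HOK,heptane,-17.834
N10,3HAA,heptane,-27.015
N10,3HAAi,heptane,-36.704
N10,2AP,water,-16.072
N10,L3HOK,water,-15.064
N10,3HAA,water,-23.525
N10,3HAAi,water,-29.964
N11,2AP,gas,50.631
N11,L3HOK,gas,51.287
N11,3HAA,gas,49.565
N11,3HAAi,gas,35.053
N11,2AP,heptane,48.166
N11,L3HOK,heptane,49.646
N11,3HAA,heptane,48.05
N11,3HAAi,heptane,36.181
N11,2AP,water,47.326
N11,L3HOK,water,49.746
N11,3HAA,water,48.6
N11,3HAAi,water,42.591
N12,2AP,gas,60.238
N12,L3HOK,gas,54.177
N12,3HAA,gas,66.544
N12,3HAAi,gas,65.835
N12,2AP,heptane,62.874
N12,L3HOK,heptane,56.955
N12,3HAA,heptane,68.334
N12,3HAAi,heptane,68.114
N12,2AP,water,64.904
N12,L3HOK,water,58.295
N12,3HAA,water,67.754
N12,3HAAi,water,68.024
N13,2AP,gas,-235.127
N13,L3HOK,gas,-227.299
N13,3HAA,gas,-236.913
N13,3HAAi,gas,-376.557
N13,2AP,water,-8.572
N13,L3HOK,water,4.544
N13,3HAA,water,-7.148
N13,3HAAi,water,-14.534
N14,2AP,gas,219.543
N14,L3HOK,gas,225.868
N14,3HAA,gas,231.321
N14,3HAAi,gas,382.735
N14,2AP,water,-4.131
N14,L3HOK,water,-5.72
N14,3HAA,water,1.778
N14,3HAAi,water,15.35
N7+8,2AP,gas,-8.876
N7+8,L3HOK,gas,-7.831
N7+8,3HAA,gas,-12.434
N7+8,3HAAi,gas,-1.684
N7+8,2AP,heptane,-8.341
N7+8,L3HOK,heptane,-7.128
N7+8,3HAA,heptane,-10.699
N7+8,3HAAi,heptane,-3.52
N7+8,2AP,water,-7.231
N7+8,L3HOK,water,-6.618
N7+8,3HAA,water,-7.489
N7+8,3HAAi,water,-6.36
N13+14,2AP,gas,-15.584
N13+14,L3HOK,gas,-1.431
N13+14,3HAA,gas,-5.592
N13+14,3HAAi,gas,6.178
N13+14,2AP,heptane,-14.643
N13+14,L3HOK,heptane,-1.326
N13+14,3HAA,heptane,-5.48
N13+14,3HAAi,heptane,4.886
N13+14,2AP,water,-12.703
N13+14,L3HOK,water,-1.176
N13+14,3HAA,water,-5.37
N13+14,3HAAi,water,0.816
N15,2AP,gas,5.428
N15,L3HOK,gas,2.868
N15,3HAA,gas,-5.04
N15,3HAAi,gas,58.242
N15,2AP,heptane,6.752
N15,L3HOK,heptane,5.432
N15,3HAA,heptane,-2.399
N15,3HAAi,heptane,35.867
N15,2AP,water,6.932
N15,L3HOK,water,5.702
N15,3HAA,water,-0.209
N15,3HAAi,water,9.317
N16,2AP,gas,35.327
N16,L3HOK,gas,39.935
N16,3HAA,gas,39.98
N16,3HAAi,gas,33.985
N16,2AP,heptane,33.408
N16,L3HOK,heptane,38.635
N16,3HAA,heptane,38.624
N16,3HAAi,heptane,31.403
N16,2AP,water,33.628
N16,L3HOK,water,38.125
N16,3HAA,water,38.734
N16,3HAAi,water,31.613
N17,2AP,gas,24.239
N17,L3HOK,gas,22.606
N17,3HAA,gas,27.997
N17,3HAAi,gas,39.903
N17,2AP,heptane,26.58
N17,L3HOK,heptane,25.026
N17,3HAA,heptane,29.118
N17,3HAAi,heptane,40.849
N17,2AP,water,28.48
N17,L3HOK,water,29.126
N17,3HAA,water,30.098
N17,3HAAi,water,38.789
N18,2AP,gas,-15.386
N18,L3HOK,gas,0.726
N18,3HAA,gas,-8.522
N18,3HAAi,gas,-0.379
N18,2AP,heptane,-15.931
N18,L3HOK,heptane,-0.344
N18,3HAA,heptane,-9.522
N18,3HAAi,heptane,-3.639
N18,2AP,water,-16.271
N18,L3HOK,water,-4.994
N18,3HAA,water,-11.032
N18,3HAAi,water,-10.129
N19,2AP,gas,50.713
N19,L3HOK,gas,37.503
N19,3HAA,gas,48.502
N19,3HAAi,gas,34.364
N19,2AP,heptane,49.339
N19,L3HOK,heptane,35.929
N19,3HAA,heptane,48.146
N19,3HAAi,heptane,35.042
N19,2AP,water,49.899
N19,L3HOK,water,43.119
N19,3HAA,water,49.766
N19,3HAAi,water,41.742
N20,2AP,gas,5.19
N20,L3HOK,gas,4.041
N20,3HAA,gas,8.872
N20,3HAAi,gas,14.155
N20,2AP,heptane,5.105
N20,L3HOK,heptane,1.883
N20,3HAA,heptane,7.735
N20,3HAAi,heptane,13.768
N20,2AP,water,5.405
N20,L3HOK,water,3.533
N20,3HAA,water,7.455
N20,3HAAi,water,12.228
N21,2AP,gas,19.049
N21,L3HOK,gas,20.27
N21,3HAA,gas,19.125
N21,3HAAi,gas,25.749
N21,2AP,heptane,21.475
N21,L3HOK,heptane,23.143
N21,3HAA,heptane,21.383
N21,3HAAi,heptane,27.081
N21,2AP,water,23.075
N21,L3HOK,water,25.593
N21,3HAA,water,22.643
N21,3HAAi,water,26.561
N22,2AP,gas,71.086
N22,L3HOK,gas,68.879
N22,3HAA,gas,77.053
N22,3HAAi,gas,75.047
N22,2AP,heptane,73.744
N22,L3HOK,heptane,69.126
N22,3HAA,heptane,79.402
N22,3HAAi,heptane,87.462
N22,2AP,water,74.794
N22,L3HOK,water,70.766
N22,3HAA,water,79.412
N22,3HAAi,water,86.462
N23,2AP,gas,11.885
N23,L3HOK,gas,21.032
N23,3HAA,gas,12.269
N23,3HAAi,gas,18.802
N23,2AP,heptane,7.935
N23,L3HOK,heptane,17.277
N23,3HAA,heptane,7.251
N23,3HAAi,heptane,8.108
N23,2AP,water,8.645
N23,L3HOK,water,17.377
N23,3HAA,water,6.901
N23,3HAAi,water,4.088
N24,2AP,gas,-58.732
N24,L3HOK,gas,-65.6
N24,3HAA,gas,-61.325
N24,3HAAi,gas,-53.945
N24,2AP,heptane,-55.099
N24,L3HOK,heptane,-61.377
N24,3HAA,heptane,-57.535
N24,3HAAi,heptane,-54.721
N24,2AP,water,-54.959
N24,L3HOK,water,-59.017
N24,3HAA,water,-56.215
N24,3HAAi,water,-51.761
N25,2AP,gas,-25.605
N25,L3HOK,gas,-32.475
N25,3HAA,gas,-41.827
N25,3HAAi,gas,-46.264
N25,2AP,heptane,-26.756
N25,L3HOK,heptane,-32.486
N25,3HAA,heptane,-41.471
N25,3HAAi,heptane,-45.919
N25,2AP,water,-29.126
N25,L3HOK,water,-31.526
N25,3HAA,water,-39.741
N25,3HAAi,water,-42.279
N26_NH4,L3HOK,gas,144.553
N26_NH4,L3HOK,heptane,108.357
N26_NH4,L3HOK,water,76.563
N26_NH3,L3HOK,gas,85.749
N26_NH3,L3HOK,heptane,85.895
N26_NH3,L3HOK,water,84.415
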