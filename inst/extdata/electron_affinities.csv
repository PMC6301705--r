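form,compound,phase,EA,anion_optimized_in
M,2AP,gas,-17.431,gas
M,L3HOK,gas,7.141,gas
M,3HAA,gas,1.481,gas
M,3HAAi,gas,-74.436,gas
M,2AP,heptane,-0.072,gas
M,L3HOK,heptane,29.794,gas
M,3HAA,heptane,25.565,gas
M,3HAAi,heptane,-32.667,gas
M,2AP,water,24.818,gas
M,L3HOK,water,55.874,gas
M,3HAA,water,51.965,gas
M,3HAAi,water,16.333,gas
Mstar,2AP,gas,36.773,gas
Mstar,L3HOK,gas,46.724,gas
Mstar,3HAA,gas,49.904,water
Mstar,3HAAi,gas,-43.573,gas
Mstar,2AP,heptane,59.4,gas
Mstar,L3HOK,heptane,66.802,gas
Mstar,3HAA,heptane,70.871,water
Mstar,3HAAi,heptane,17.558,gas
Mstar,2AP,water,87.37,gas
Mstar,L3HOK,water,92.202,gas
Mstar,3HAA,water,97.041,water
Mstar,3HAAi,water,85.938,gas
Mq,2AP,gas,40.629,gas
Mq,L3HOK,gas,56.762,gas
Mq,3HAA,gas,52.249,gas
Mq,3HAAi,gas,-41.936,gas
Mq,2AP,heptane,66.755,gas
Mq,L3HOK,heptane,77.456,gas
Mq,3HAA,heptane,75.648,gas
Mq,3HAAi,heptane,22.861,gas
Mq,2AP,water,93.995,gas
Mq,L3HOK,water,98.566,gas
Mq,3HAA,water,99.678,gas
Mq,3HAAi,water,90.601,gas
D1,2AP,gas,15.388,gas
D1,L3HOK,gas,39.966,gas
D1,3HAA,gas,41.352,gas
D1,3HAAi,gas,-106.854,gas
D1,2AP,heptane,38.58,gas
D1,L3HOK,heptane,58.428,gas
D1,3HAA,heptane,60.527,gas
D1,3HAAi,heptane,-22.479,gas
D1,2AP,water,64.88,gas
D1,L3HOK,water,77.958,gas
D1,3HAA,water,80.177,gas
D1,3HAAi,water,66.781,gas
D2,2AP,gas,-10.561,gas
D2,L3HOK,gas,22.615,gas
D2,3HAA,gas,13.775,gas
D2,3HAAi,gas,-109.852,water
D2,2AP,heptane,4.591,gas
D2,L3HOK,heptane,40.39,gas
D2,3HAA,heptane,33.802,gas
D2,3HAAi,heptane,-48.2,water
D2,2AP,water,26.731,gas
D2,L3HOK,water,59.44,gas
D2,3HAA,water,56.422,gas
D2,3HAAi,water,30.31,water
D3,2AP,gas,33.655,gas
D3,L3HOK,gas,47.391,gas
D3,3HAA,gas,42.839,gas
D3,3HAAi,gas,-90.037,gas
D3,2AP,heptane,53.346,gas
D3,L3HOK,heptane,62.764,gas
D3,3HAA,heptane,60.205,gas
D3,3HAAi,heptane,-9.404,gas
D3,2AP,water,79.336,gas
D3,L3HOK,water,82.734,gas
D3,3HAA,water,83.125,gas
D3,3HAAi,water,79.486,gas
D4,2AP,gas,36.309,gas
D4,L3HOK,gas,54.684,gas
D4,3HAA,gas,47.059,gas
D4,3HAAi,gas,-92.084,gas
D4,2AP,heptane,60.025,gas
D4,L3HOK,heptane,72.552,gas
D4,3HAA,heptane,67.666,gas
D4,3HAAi,heptane,-6.092,gas
D4,2AP,water,86.635,gas
D4,L3HOK,water,71.732,gas
D4,3HAA,water,90.486,gas
D4,3HAAi,water,85.608,gas
D5,2AP,gas,39.123,gas
D5,L3HOK,gas,52.428,gas
D5,3HAA,gas,55.737,gas
D5,3HAAi,gas,-90.281,gas
D5,2AP,heptane,61.768,gas
D5,L3HOK,heptane,70.691,gas
D5,3HAA,heptane,74.807,gas
D5,3HAAi,heptane,-5.238,gas
D5,2AP,water,87.248,gas
D5,L3HOK,water,91.141,gas
D5,3HAA,water,94.557,gas
D5,3HAAi,water,85.722,gas
D6,2AP,gas,17.741,gas
D6,L3HOK,gas,41.744,gas
D6,3HAA,gas,31.103,gas
D6,3HAAi,gas,-104.878,gas
D6,2AP,heptane,39.556,gas
D6,L3HOK,heptane,57.051,gas
D6,3HAA,heptane,50.309,gas
D6,3HAAi,heptane,-5.908,gas
D6,2AP,water,63.466,gas
D6,L3HOK,water,72.411,gas
D6,3HAA,water,71.039,gas
D6,3HAAi,water,59.572,gas
D7,2AP,gas,-11.311,gas
D7,L3HOK,gas,25.482,gas
D7,3HAA,gas,16.666,gas
D7,3HAAi,gas,-108.281,water
D7,2AP,heptane,4.698,gas
D7,L3HOK,heptane,42.627,gas
D7,3HAA,heptane,36.352,gas
D7,3HAAi,heptane,-46.753,water
D7,2AP,water,27.128,gas
D7,L3HOK,water,61.107,gas
D7,3HAA,water,57.402,gas
D7,3HAAi,water,28.397,water
D8,2AP,gas,35.01,gas
D8,L3HOK,gas,50.54,gas
D8,3HAA,gas,46.31,gas
D8,3HAAi,gas,-96.759,gas
D8,2AP,heptane,53.907,gas
D8,L3HOK,heptane,65.201,gas
D8,3HAA,heptane,62.897,gas
D8,3HAAi,heptane,-14.847,gas
D8,2AP,water,78.207,gas
D8,L3HOK,water,84.581,gas
D8,3HAA,water,84.057,gas
D8,3HAAi,water,75.203,gas
D9,2AP,gas,36.472,gas
D9,L3HOK,gas,52.328,gas
D9,3HAA,gas,48.91,gas
D9,3HAAi,gas,-96.318,gas
D9,2AP,heptane,59.149,gas
D9,L3HOK,heptane,70.003,gas
D9,3HAA,heptane,68.486,gas
D9,3HAAi,heptane,-10.766,gas
D9,2AP,water,83.819,gas
D9,L3HOK,water,86.873,gas
D9,3HAA,water,89.126,gas
D9,3HAAi,water,78.984,gas
D10,2AP,gas,37.87,gas
D10,L3HOK,gas,51.532,gas
D10,3HAA,gas,49.163,gas
D10,3HAAi,gas,-90.484,gas
D10,2AP,heptane,60.674,gas
D10,L3HOK,heptane,68.895,gas
D10,3HAA,heptane,68.277,gas
D10,3HAAi,heptane,-6.589,gas
D10,2AP,water,84.684,gas
D10,L3HOK,water,87.875,gas
D10,3HAA,water,89.017,gas
D10,3HAAi,water,81.701,gas
D1p,2AP,gas,49.739,gas
D1p,L3HOK,gas,61.771,gas
D1p,3HAA,gas,56.314,gas
D1p,3HAAi,gas,-86.567,gas
D1p,2AP,heptane,71.139,gas
D1p,L3HOK,heptane,77.774,gas
D1p,3HAA,heptane,68.723,gas
D1p,3HAAi,heptane,-2.12,gas
D1p,2AP,water,93.579,gas
D1p,L3HOK,water,94.794,gas
D1p,3HAA,water,97.113,gas
D1p,3HAAi,water,86.86,gas
D3p,2AP,gas,68.794,gas
D3p,L3HOK,gas,68.297,gas
D3p,3HAA,gas,63.722,gas
D3p,3HAAi,gas,-82.331,gas
D3p,2AP,heptane,86.455,gas
D3p,L3HOK,heptane,82.723,gas
D3p,3HAA,heptane,79.801,gas
D3p,3HAAi,heptane,-2.2,gas
D3p,2AP,water,107.455,gas
D3p,L3HOK,water,100.673,gas
D3p,3HAA,water,99.551,gas
D3p,3HAAi,water,87.08,gas
XAN,L3HOK,gas,63.213,gas
XAN,L3HOK,heptane,81.117,gas
XAN,L3HOK,water,98.097,gas
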