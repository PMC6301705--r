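form,compound,phase,IP,cation_optimized_in
M,2AP,gas,164.117,gas
M,L3HOK,gas,162.258,gas
M,3HAA,gas,169.726,gas
M,3HAAi,gas,74.475,water
M,2AP,heptane,138.501,gas
M,L3HOK,heptane,140.417,gas
M,3HAA,heptane,144.833,gas
M,3HAAi,heptane,107.384,water
M,2AP,water,115.721,gas
M,L3HOK,water,120.737,gas
M,3HAA,water,121.873,gas
M,3HAAi,water,130.254,water
Mstar,2AP,gas,169.569,gas
Mstar,L3HOK,gas,164.544,gas
Mstar,3HAA,gas,173.667,gas
Mstar,3HAAi,gas,109.935,water
Mstar,2AP,heptane,147.295,gas
Mstar,L3HOK,heptane,145.826,gas
Mstar,3HAA,heptane,151.607,gas
Mstar,3HAAi,heptane,101.612,water
Mstar,2AP,water,122.955,gas
Mstar,L3HOK,water,124.966,gas
Mstar,3HAA,water,126.967,gas
Mstar,3HAAi,water,119.232,water
Mq,2AP,gas,225.274,water
Mq,L3HOK,gas,187.688,gas
Mq,3HAA,gas,206.433,gas
Mq,3HAAi,gas,106.97,gas
Mq,2AP,heptane,182.763,water
Mq,L3HOK,heptane,163.596,gas
Mq,3HAA,heptane,181.238,gas
Mq,3HAAi,heptane,127.181,gas
Mq,2AP,water,155.263,water
Mq,L3HOK,water,141.026,gas
Mq,3HAA,water,157.728,gas
Mq,3HAAi,water,150.671,gas
D1,2AP,gas,156.054,gas
D1,L3HOK,gas,162.435,gas
D1,3HAA,gas,161.459,gas
D1,3HAAi,gas,30.6,water
D1,2AP,heptane,134.58,gas
D1,L3HOK,heptane,142.91,gas
D1,3HAA,heptane,140.259,gas
D1,3HAAi,heptane,43.143,water
D1,2AP,water,115.42,gas
D1,L3HOK,water,123.09,gas
D1,3HAA,water,120.459,gas
D1,3HAAi,water,118.883,water
D2,2AP,gas,142.385,gas
D2,L3HOK,gas,150.01,gas
D2,3HAA,gas,146.307,gas
D2,3HAAi,gas,1.699,gas
D2,2AP,heptane,122.551,gas
D2,L3HOK,heptane,129.424,gas
D2,3HAA,heptane,126.682,gas
D2,3HAAi,heptane,52.704,gas
D2,2AP,water,106.381,gas
D2,L3HOK,water,111.004,gas
D2,3HAA,water,109.632,gas
D2,3HAAi,water,111.186,gas
D3,2AP,gas,139.983,gas
D3,L3HOK,gas,146.549,gas
D3,3HAA,gas,144.102,gas
D3,3HAAi,gas,0.957,water
D3,2AP,heptane,123.507,gas
D3,L3HOK,heptane,130.27,gas
D3,3HAA,heptane,127.607,gas
D3,3HAAi,heptane,51.781,water
D3,2AP,water,107.087,gas
D3,L3HOK,water,112.58,gas
D3,3HAA,water,110.387,gas
D3,3HAAi,water,103.471,water
D4,2AP,gas,166.378,gas
D4,L3HOK,gas,169.757,gas
D4,3HAA,gas,172.613,gas
D4,3HAAi,gas,20.42,gas
D4,2AP,heptane,143.98,gas
D4,L3HOK,heptane,151.663,gas
D4,3HAA,heptane,152.408,gas
D4,3HAAi,heptane,69.743,gas
D4,2AP,water,123.16,gas
D4,L3HOK,water,136.193,gas
D4,3HAA,water,133.798,gas
D4,3HAAi,water,124.433,gas
D5,2AP,gas,159.845,gas
D5,L3HOK,gas,165.277,gas
D5,3HAA,gas,165.407,gas
D5,3HAAi,gas,14.903,gas
D5,2AP,heptane,139.689,gas
D5,L3HOK,heptane,145.243,gas
D5,3HAA,heptane,145.302,gas
D5,3HAAi,heptane,63.685,gas
D5,2AP,water,122.109,gas
D5,L3HOK,water,125.553,gas
D5,3HAA,water,127.202,gas
D5,3HAAi,water,117.805,gas
D6,2AP,gas,151.876,gas
D6,L3HOK,gas,160.487,gas
D6,3HAA,gas,161.285,gas
D6,3HAAi,gas,12.474,water
D6,2AP,heptane,131.272,gas
D6,L3HOK,heptane,143.122,gas
D6,3HAA,heptane,140.982,gas
D6,3HAAi,heptane,59.322,water
D6,2AP,water,113.532,gas
D6,L3HOK,water,127.202,gas
D6,3HAA,water,123.182,gas
D6,3HAAi,water,107.582,gas
D7,2AP,gas,137.538,gas
D7,L3HOK,gas,141.94,gas
D7,3HAA,gas,142.197,gas
D7,3HAAi,gas,-3.135,gas
D7,2AP,heptane,117.519,gas
D7,L3HOK,heptane,123.958,gas
D7,3HAA,heptane,122.506,gas
D7,3HAAi,heptane,43.822,gas
D7,2AP,water,100.099,gas
D7,L3HOK,water,107.858,gas
D7,3HAA,water,104.706,gas
D7,3HAAi,water,94.892,gas
D8,2AP,gas,140.693,gas
D8,L3HOK,gas,142.364,gas
D8,3HAA,gas,145.311,gas
D8,3HAAi,gas,2.965,water
D8,2AP,heptane,123.214,gas
D8,L3HOK,heptane,112.536,gas
D8,3HAA,heptane,127.942,gas
D8,3HAAi,heptane,51.915,water
D8,2AP,water,104.534,gas
D8,L3HOK,water,110.976,gas
D8,3HAA,water,108.902,gas
D8,3HAAi,water,99.715,water
D9,2AP,gas,173.081,gas
D9,L3HOK,gas,174.437,gas
D9,3HAA,gas,180.871,gas
D9,3HAAi,gas,24.029,water
D9,2AP,heptane,150.194,gas
D9,L3HOK,heptane,155.376,gas
D9,3HAA,heptane,159.439,gas
D9,3HAAi,heptane,71.278,water
D9,2AP,water,127.244,gas
D9,L3HOK,water,139.246,gas
D9,3HAA,water,138.649,gas
D9,3HAAi,water,121.068,water
D10,2AP,gas,170.51,gas
D10,L3HOK,gas,168.494,gas
D10,3HAA,gas,177.467,gas
D10,3HAAi,gas,15.375,gas
D10,2AP,heptane,149.212,gas
D10,L3HOK,heptane,148.562,gas
D10,3HAA,heptane,156.456,gas
D10,3HAAi,heptane,64.426,gas
D10,2AP,water,128.922,gas
D10,L3HOK,water,130.882,gas
D10,3HAA,water,136.526,gas
D10,3HAAi,water,117.186,gas
D1p,2AP,gas,170.472,gas
D1p,L3HOK,gas,171.145,gas
D1p,3HAA,gas,178.118,gas
D1p,3HAAi,gas,19.18,gas
D1p,2AP,heptane,148.452,gas
D1p,L3HOK,heptane,152.327,gas
D1p,3HAA,heptane,157.187,gas
D1p,3HAAi,heptane,68.41,gas
D1p,2AP,water,128.142,gas
D1p,L3HOK,water,134.087,gas
D1p,3HAA,water,138.877,gas
D1p,3HAAi,water,126.49,gas
D3p,2AP,gas,145.886,gas
D3p,L3HOK,gas,152.647,gas
D3p,3HAA,gas,154.275,gas
D3p,3HAAi,gas,12.897,gas
D3p,2AP,heptane,129.193,gas
D3p,L3HOK,heptane,138.12,gas
D3p,3HAA,heptane,137.437,gas
D3p,3HAAi,heptane,64.334,gas
D3p,2AP,water,110.863,gas
D3p,L3HOK,water,122.41,gas
D3p,3HAA,water,119.677,gas
D3p,3HAAi,water,116.354,gas
XAN,L3HOK,gas,178.983,gas
XAN,L3HOK,heptane,158.372,gas
XAN,L3HOK,water,140.052,gas
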