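compound,phase,total
2AP,gas,310.254
L3HOK,gas,317.589
3HAA,gas,325.738
3HAAi,gas,370.475
2AP,heptane,313.132
L3HOK,heptane,323.371
3HAA,heptane,329.303
3HAAi,heptane,352.421
2AP,water,319.672
L3HOK,water,330.631
3HAA,water,334.283
3HAAi,water,333.481
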