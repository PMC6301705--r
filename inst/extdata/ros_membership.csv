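phase,reduction,stages,compound
gas,H2O2,N5+6,3HAAi
gas,H2O2,N11+12,L3HOK
gas,H2O2,N11+12,3HAAi
gas,H2O2,N19+22,L3HOK
gas,HO2,N11,3HAAi
gas,HO2,N16,2AP
gas,HO2,N16,3HAAi
gas,HO2,N17,2AP
gas,HO2,N17,L3HOK
gas,HO2,N17,3HAA
gas,HO2,N19,L3HOK
gas,HO2,N19,3HAAi
gas,HO2,N21,2AP
gas,HO2,N21,L3HOK
gas,HO2,N21,3HAA
gas,HO2,N21,3HAAi
heptane,H2O2,N11+12,3HAAi
heptane,H2O2,N19+22,L3HOK
heptane,HO2,N11,3HAAi
heptane,HO2,N16,2AP
heptane,HO2,N16,3HAAi
heptane,HO2,N17,2AP
heptane,HO2,N17,L3HOK
heptane,HO2,N17,3HAA
heptane,HO2,N19,L3HOK
heptane,HO2,N19,3HAAi
heptane,HO2,N21,2AP
heptane,HO2,N21,L3HOK
heptane,HO2,N21,3HAA
heptane,HO2,N21,3HAAi
water,H2O2,N11+12,L3HOK
water,H2O2,N11+12,3HAAi
water,H2O2,N26,L3HOK
water,HO2,N16,2AP
water,HO2,N16,L3HOK
water,HO2,N16,3HAA
water,HO2,N16,3HAAi
water,HO2,N17,2AP
water,HO2,N17,L3HOK
water,HO2,N17,3HAA
water,HO2,N17,3HAAi
water,HO2,N21,2AP
water,HO2,N21,L3HOK
water,HO2,N21,3HAA
water,HO2,N21,3HAAi
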