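stage,rclass,role,species,count,compounds
N1,H_ABSTRACTION,reactant,M,1,2AP|L3HOK|3HAA|3HAAi
N1,H_ABSTRACTION,product,Mstar,1,2AP|L3HOK|3HAA|3HAAi
N1,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N2,H_ABSTRACTION,reactant,Mstar,1,2AP|L3HOK|3HAA|3HAAi
N2,H_ABSTRACTION,product,Mq,1,2AP|L3HOK|3HAA|3HAAi
N2,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N3,CONJUGATION,reactant,M,1,2AP|L3HOK|3HAA|3HAAi
N3,CONJUGATION,reactant,Mq,1,2AP|L3HOK|3HAA|3HAAi
N3,CONJUGATION,product,D1,1,2AP|L3HOK|3HAA|3HAAi
N4,TAUTOMERIZATION,reactant,D1,1,2AP|L3HOK|3HAA|3HAAi
N4,TAUTOMERIZATION,product,D2,1,2AP|L3HOK|3HAA|3HAAi
N5,H_ABSTRACTION,reactant,D2,1,2AP|L3HOK|3HAA|3HAAi
N5,H_ABSTRACTION,product,D3,1,2AP|L3HOK|3HAA|3HAAi
N5,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N6,H_ABSTRACTION,reactant,D3,1,2AP|L3HOK|3HAA|3HAAi
N6,H_ABSTRACTION,product,D4,1,2AP|L3HOK|3HAA|3HAAi
N6,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N7,PROTONATION,reactant,D4,1,2AP|L3HOK|3HAA|3HAAi
N7,PROTONATION,reactant,Hplus,1,2AP|L3HOK|3HAA|3HAAi
N7,PROTONATION,product,D4H,1,2AP|L3HOK|3HAA|3HAAi
N8,DEPROTONATION,reactant,D4H,1,2AP|L3HOK|3HAA|3HAAi
N8,DEPROTONATION,product,D5,1,2AP|L3HOK|3HAA|3HAAi
N8,DEPROTONATION,product,Hplus,1,2AP|L3HOK|3HAA|3HAAi
N9,CYCLIZATION,reactant,D5,1,2AP|L3HOK|3HAA|3HAAi
N9,CYCLIZATION,product,D6,1,2AP|L3HOK|3HAA|3HAAi
N10,TAUTOMERIZATION,reactant,D6,1,2AP|L3HOK|3HAA|3HAAi
N10,TAUTOMERIZATION,product,D7,1,2AP|L3HOK|3HAA|3HAAi
N11,H_ABSTRACTION,reactant,D7,1,2AP|L3HOK|3HAA|3HAAi
N11,H_ABSTRACTION,product,D8,1,2AP|L3HOK|3HAA|3HAAi
N11,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N12,H_ABSTRACTION,reactant,D8,1,2AP|L3HOK|3HAA|3HAAi
N12,H_ABSTRACTION,product,D9,1,2AP|L3HOK|3HAA|3HAAi
N12,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N13,PROTONATION,reactant,D9,1,2AP|L3HOK|3HAA|3HAAi
N13,PROTONATION,reactant,Hplus,1,2AP|L3HOK|3HAA|3HAAi
N13,PROTONATION,product,D9H,1,2AP|L3HOK|3HAA|3HAAi
N14,DEPROTONATION,reactant,D9H,1,2AP|L3HOK|3HAA|3HAAi
N14,DEPROTONATION,product,D10,1,2AP|L3HOK|3HAA|3HAAi
N14,DEPROTONATION,product,Hplus,1,2AP|L3HOK|3HAA|3HAAi
N15,CONJUGATION,reactant,Mq,2,2AP|L3HOK|3HAA|3HAAi
N15,CONJUGATION,product,D1p,1,2AP|L3HOK|3HAA|3HAAi
N16,H_ABSTRACTION,reactant,D1p,1,2AP|L3HOK|3HAA|3HAAi
N16,H_ABSTRACTION,product,D3p,1,2AP|L3HOK|3HAA|3HAAi
N16,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N17,H_ABSTRACTION,reactant,D3p,1,2AP|L3HOK|3HAA|3HAAi
N17,H_ABSTRACTION,product,D10,1,2AP|L3HOK|3HAA|3HAAi
N17,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N18,TAUTOMERIZATION,reactant,D1p,1,2AP|L3HOK|3HAA|3HAAi
N18,TAUTOMERIZATION,product,D2p,1,2AP|L3HOK|3HAA|3HAAi
N19,H_ABSTRACTION,reactant,D2p,1,2AP|L3HOK|3HAA|3HAAi
N19,H_ABSTRACTION,product,D3p,1,2AP|L3HOK|3HAA|3HAAi
N19,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N20,CYCLIZATION,reactant,D3p,1,2AP|L3HOK|3HAA|3HAAi
N20,CYCLIZATION,product,D5p,1,2AP|L3HOK|3HAA|3HAAi
N21,H_ABSTRACTION,reactant,D5p,1,2AP|L3HOK|3HAA|3HAAi
N21,H_ABSTRACTION,product,D10,1,2AP|L3HOK|3HAA|3HAAi
N21,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N22,H_ABSTRACTION,reactant,D3p,1,2AP|L3HOK|3HAA|3HAAi
N22,H_ABSTRACTION,product,D4p,1,2AP|L3HOK|3HAA|3HAAi
N22,H_ABSTRACTION,product,Hstar,1,2AP|L3HOK|3HAA|3HAAi
N23,CYCLIZATION,reactant,D4p,1,2AP|L3HOK|3HAA|3HAAi
N23,CYCLIZATION,product,D6p,1,2AP|L3HOK|3HAA|3HAAi
N24,TAUTOMERIZATION,reactant,D6p,1,2AP|L3HOK|3HAA|3HAAi
N24,TAUTOMERIZATION,product,D10,1,2AP|L3HOK|3HAA|3HAAi
N25,TAUTOMERIZATION,reactant,D5p,1,2AP|L3HOK|3HAA|3HAAi
N25,TAUTOMERIZATION,product,D8,1,2AP|L3HOK|3HAA|3HAAi
N26_NH4,CYCLIZATION,reactant,D10,1,L3HOK
N26_NH4,CYCLIZATION,product,XAN,1,L3HOK
N26_NH4,CYCLIZATION,product,NH4p,1,L3HOK
N26_NH4,CYCLIZATION,product,Hstar,2,L3HOK
N26_NH3,CYCLIZATION,reactant,D10,1,L3HOK
N26_NH3,CYCLIZATION,product,XAN,1,L3HOK
N26_NH3,CYCLIZATION,product,NH3,1,L3HOK
N26_NH3,CYCLIZATION,product,Hstar,2,L3HOK
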