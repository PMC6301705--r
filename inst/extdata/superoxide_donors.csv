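phase,compound,form
gas,3HAAi,D2
gas,3HAAi,D3
gas,3HAAi,D4
gas,3HAAi,D7
gas,3HAAi,D8
gas,3HAAi,D3p
heptane,3HAAi,D1
heptane,3HAAi,D2
heptane,3HAAi,D3
heptane,3HAAi,D4
heptane,3HAAi,D5
heptane,3HAAi,D6
heptane,3HAAi,D7
heptane,3HAAi,D8
heptane,3HAAi,D9
heptane,3HAAi,D10
heptane,3HAAi,D1p
heptane,3HAAi,D3p
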