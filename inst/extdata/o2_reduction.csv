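"phase","reduction","half_reaction","dG","n_h"
"gas","full","1.5 O2 + 6H* -> 3H2O","-416.754",6
"gas","H2O2","O2 + 2H* -> H2O2","-108.188",2
"gas","HO2","O2 + H* -> HO2*","-37.988",1
"gas","superoxide","O2 -> O2*-","-13.945",0
"heptane","full","1.5 O2 + 6H* -> 3H2O","-415.782",6
"heptane","H2O2","O2 + 2H* -> H2O2","-105.873",2
"heptane","HO2","O2 + H* -> HO2*","-37.687",1
"heptane","superoxide","O2 -> O2*-","-85.83",0
"water","full","3O2 + 6H* -> 3H2O","-431,358",6
"water","H2O2","O2 + 2H* -> H2O2","-111.033",2
"water","HO2","O2 + H* -> HO2*","-41.477",1
"water","superoxide","O2 -> O2*-","-87.31",0
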