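code,name
B,Blood and blood forming organs
B01,Antithrombotic agents
B01A,Antithrombotic agents
B01AA,Vitamin K antagonists
B01AA03,Warfarin
B01AC,Platelet aggregation inhibitors excluding heparin
B01AC04,Clopidogrel
B01AC05,Ticlopidine
B01AC07,Dipyridamole
B01AC23,Cilostazol
B01AC30,Combinations
A02BC01,Omeprazole
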