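site,typology,level,square,n_bones
Starosele,Starosele-Level-3-Industry,3,F21,20
Starosele,Micoquian,1,G21,20
Starosele,Micoquian,1,H23,20
Starosele,Micoquian,1,I23,70
Starosele,Micoquian,1,I22,20
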