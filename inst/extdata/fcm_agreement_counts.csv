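disinfectant,n_strains,exact_agree,within_1_dilution,within_2_dilution
Mikrozid,14,12,14,14
Klinosept,14,11,13,14
Glutanol,14,14,14,14
Peroklin,14,13,14,14
Clor2Klin,14,14,14,14
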