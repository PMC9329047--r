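campaign,species,change_mmol_m2
march,As,0.841
may,As,0.436
august,As,0.135
march,Fe,491
may,Fe,14.1
august,Fe,-45.4
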