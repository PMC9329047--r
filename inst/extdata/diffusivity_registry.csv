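species,m0,m1,note
Fe2+,3.31,0.15,Boudreau (1997) linear fit for Fe2+
Mn2+,3.18,0.155,Boudreau (1997) linear fit for Mn2+
NH4+,9.5,0.413,Boudreau (1997) linear fit for NH4+
HS-,10.4,0.273,Boudreau (1997) linear fit for HS-
H2S,11.0,0.4,linearized neutral-molecule estimate (Hayduk-Laudie anchor at 25 C)
HAsO4,3.26,0.177,HPO4 2- analog (Boudreau 1997); default species for dissolved As
H2AsO4,4.02,0.223,H2PO4- analog (Boudreau 1997)
H3AsO3,5.0,0.22,linearized neutral-molecule estimate anchored near 1.05e-5 cm2 s-1 at 25 C
O2,11.7,0.344,linearized dissolved-gas estimate for QC use
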