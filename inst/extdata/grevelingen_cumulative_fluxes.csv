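campaign,core,species,cumulative_mmol_m2
march,1,dAs,0.24
march,2,dAs,0.20
march,3,dAs,0.06
may,1,dAs,0.28
may,2,dAs,0.48
may,3,dAs,0.18
august,1,dAs,0.004
august,2,dAs,0.005
august,3,dAs,0.007
march,1,dFe,134
march,2,dFe,112
march,3,dFe,69
may,1,dFe,52
may,2,dFe,60
may,3,dFe,40
august,1,dFe,0.33
august,2,dFe,0
august,3,dFe,0.21
march,1,SumH2S,335
march,2,SumH2S,106
march,3,SumH2S,450
may,1,SumH2S,100
may,2,SumH2S,29
may,3,SumH2S,23
august,1,SumH2S,368
august,2,SumH2S,385
august,3,SumH2S,242
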