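family,n-Hexane,MeTHF,CPME,d-Limonene,p-Cymene,Ethanol
sterol,568,641,785,590,543,588
tocopherol,48,50.6,52.3,44.8,43.7,39.8
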