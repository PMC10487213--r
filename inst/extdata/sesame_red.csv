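solvent,C16:0,C18:1,C18:2,gamma-Tocopherol,beta-Sitosterol
n-Hexane,1.77,1.77,1.95,2.03,2.00
MeTHF,0.57,0.65,0.75,1.41,1.24
CPME,0.87,0.94,1.17,1.97,1.89
d-Limonene,0.73,0.68,0.82,0.31,0.30
p-Cymene,1.26,1.12,1.23,1.96,1.87
Ethanol,2.94,3.03,2.98,5.80,5.90
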