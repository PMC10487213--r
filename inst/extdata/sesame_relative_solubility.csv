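solvent,C16:0,C18:1,C18:2,gamma-Tocopherol,beta-Sitosterol
n-Hexane,-1.27,-1.34,-1.31,-0.2974,-0.8017
MeTHF,0.0,0.0,0.0,0.0,0.0
CPME,0.0,0.0,0.0,0.0,0.0
d-Limonene,-0.96,-0.98,-0.88,-0.1324,-0.6992
p-Cymene,-1.03,-1.03,-0.9,-0.2018,-0.7829
Ethanol,-0.001,-0.05,0.0,-0.8650,-0.5797
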