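parameter,unit,n-Hexane,MeTHF,CPME,d-Limonene,p-Cymene,Ethanol
acid_value,mg KOH/g oil,1.69,1.05,1.73,0.92,0.95,1.07
peroxide_value,mEq O2/kg,3.42,2.67,3.95,4.83,4.36,4.01
iodine_value,g I2/100 g,111,123,105,104,93,96
refractive_index,20 C,1.42,1.45,1.47,1.45,1.44,1.47
k232,,0.94,1.33,1.05,1.18,1.52,0.82
k270,,0.24,0.38,0.31,0.41,0.47,0.23
chlorophyll,mg/kg,2.05,1.89,1.92,2.34,2.67,1.73
oxidative_stability,h,27.83,28.34,28.56,28.05,27.30,27.04
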