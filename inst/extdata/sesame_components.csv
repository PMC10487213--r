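family,component,n-Hexane,MeTHF,CPME,d-Limonene,p-Cymene,Ethanol
sterol,Cholesterol,1.13,1.47,0.46,4.83,5.15,6.64
sterol,Campesterol,99.22,123.20,164.53,101.00,86.93,66.79
sterol,Stigmasterol,33.39,25.89,16.64,29.61,38.11,37.92
sterol,beta-Sitosterol,373.63,437.80,555.93,400.78,364.19,387.96
sterol,D5-Avenasterol,40.21,37.37,39.48,41.89,44.03,35.22
sterol,D7-Avenasterol,6.13,13.90,8.87,11.83,4.01,5.64
tocopherol,alpha-Tocopherol,1.56,1.61,62.7,1.75,0.83,1.35
tocopherol,gamma-Tocopherol,43.44,46.65,48.74,39.51,39.19,36.37
tocopherol,delta-Tocopherol,3.50,2.17,2.92,4.21,3.67,2.06
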