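variety,area,weighted_area
Vi8,18.40,20.32
Mae,16.45,18.21
Yuk,15.16,16.75
Cro,11.36,12.40
Vi4,10.81,11.86
Swt,9.51,10.68
Bol,5.65,6.33
Luc,5.39,5.95
Rom,5.15,5.60
Dor,4.79,5.23
Ext,4.18,4.60
Ver,3.78,4.21
Pho,2.74,3.02
Ner,2.72,2.96
Mor,0.95,1.07
Rod,0.40,0.44
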