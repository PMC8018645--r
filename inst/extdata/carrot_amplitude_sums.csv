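variety,sum_amplitudes,mean_printed,sd_printed,n_compounds
Vi8,103.8,2.04,1.28,51
Luc,102.2,2.00,1.24,51
Cro,101.9,2.00,1.13,51
Mae,95.7,1.88,0.91,51
Ver,94.2,1.85,1.21,51
Yuk,93.1,1.83,1.19,51
Bol,92.9,1.82,1.05,51
Rod,91.7,1.80,1.33,51
Vi4,89.4,1.75,1.02,51
Pho,75.4,1.48,0.93,51
Mor,75.2,1.47,1.01,51
Ner,73.2,1.44,0.87,51
Swt,72.9,1.43,1.23,51
Ext,72.8,1.43,1.07,51
Rom,72.0,1.41,1.06,51
Dor,68.2,1.34,0.90,51
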