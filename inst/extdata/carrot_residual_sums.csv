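code,compound,sum_abs,mean_printed,sd_printed,n_varieties
PP2,myristicin,4.14,0.83,1.01,5
S6,D-germacrene,4.13,0.83,0.95,5
T2,beta-pinene,4.12,0.82,1.18,5
S10,alpha-bisabolene,4.12,0.82,1.12,5
PP1,elemicin,3.90,0.78,0.96,5
6MM,6-methoxymellein,3.71,0.74,0.88,5
S1,beta-elemene,3.67,0.73,0.88,5
T15,cis-beta-ocimene,3.59,0.72,0.99,5
T3,sabinene,3.31,0.66,0.94,5
T5,beta-myrcene,3.08,0.62,0.71,5
T18,unknown,3.06,0.61,0.77,5
T1,alpha-pinene,2.99,0.60,0.76,5
FaDOAc,falcarindiol-acetate,2.88,0.58,0.74,5
S5,E-beta-farnesene,2.77,0.55,0.69,5
T16,trans-beta-ocimene,2.64,0.53,0.72,5
S2,beta-caryophyllene,2.62,0.52,0.65,5
S11,bisabolol,2.53,0.51,0.61,5
acar,alpha-carotene,2.37,0.47,0.65,5
T17,unknown,2.36,0.47,0.64,5
S4,alpha-humulene,2.21,0.44,0.61,5
S9,gamma-bisabolene,2.05,0.41,0.55,5
FaDOH,falcarindiol,1.98,0.40,0.50,5
T14,beta-phellandrene,1.95,0.39,0.56,5
FaOH,falcarinol,1.94,0.39,0.45,5
SAC,sucrose,1.93,0.39,0.45,5
T7,gamma-terpinene,1.79,0.36,0.44,5
S13,unknown,1.78,0.36,0.49,5
T8,p-cymene,1.77,0.35,0.42,5
CIT,citric-acid,1.76,0.35,0.44,5
T6,limonene,1.72,0.34,0.43,5
lut,lutein,1.60,0.32,0.47,5
S7,beta-bisabolene,1.59,0.32,0.45,5
GLU,glucose,1.52,0.30,0.35,5
T9,alpha-terpinolene,1.48,0.30,0.40,5
T4,alpha-phellandrene,1.41,0.28,0.40,5
Bcar,beta-carotene,1.39,0.28,0.38,5
MAL,malic-acid,1.33,0.27,0.41,5
FRU,fructose,0.97,0.19,0.27,5
S3,beta-farnesene,0.96,0.19,0.24,5
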