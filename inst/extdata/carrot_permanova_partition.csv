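term,df,sum_sq,mean_sq_printed,ms_share_printed,r2_printed,f_printed
Locations,2,0.7479,0.3740,58.87,0.14063,45.8619
Varieties,15,3.394,0.2263,35.62,0.6382,27.7502
Interaction,30,0.7848,0.0267,4.2,0.14758,3.2085
Residuals,48,0.3914,0.0082,1.31,0.07359,NA
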