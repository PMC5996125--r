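region,Tinf_R,TMd_R,TSp_R,Fu_R,Hipp_R,Am_R
Fu_R,10.00,11.66,5.64,0.00,0.00,0.00
Oinf_R,28.21,25.09,27.86,7.59,3.01,0.00
Omd_R,0.00,3.43,7.95,0.00,0.00,0.00
Osp_R,0.00,0.00,0.00,0.00,0.00,0.00
Cal_R,12.41,16.06,12.14,2.90,0.00,3.71
Cun_R,0.95,0.00,0.00,0.00,0.00,0.61
Lin_R,48.77,88.66,41.34,13.48,0.00,3.65
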