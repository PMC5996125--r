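region,Tinf_R,TMd_R,TSp_R,Fu_R,Am_R
Fu_R,0.00,11.12,6.89,0.00,0.00
Oinf_R,11.35,18.75,26.82,5.52,0.00
Omd_R,0.00,0.00,9.74,0.00,0.00
Osp_R,5.67,8.39,10.28,0.00,0.00
Cal_R,11.46,15.90,14.45,0.00,5.29
Cun_R,0.00,8.26,21.75,0.00,0.00
Lin_R,41.05,77.54,40.70,14.26,5.90
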