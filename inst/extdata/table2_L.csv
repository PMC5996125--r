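region,Tinf_L,TMd_L,TSp_L,Fu_L,Hipp_L,Am_L
Fu_L,13.88,15.13,3.30,0.00,0.00,0.00
Oinf_L,37.83,40.89,35.62,3.92,0.00,0.00
Omd_L,24.72,32.87,46.50,0.00,0.00,0.00
Osp_L,3.28,5.98,0.00,0.00,0.00,0.00
Cal_L,55.24,63.17,58.29,3.58,0.00,0.00
Cun_L,6.83,6.35,0.00,0.00,0.00,0.00
Lin_L,64.86,100.00,74.63,7.02,0.00,0.00
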