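region,Tinf_L,TMd_L,TSp_L,Fu_L,Am_L
Fu_L,8.35,10.48,0.00,0.00,0.00
Oinf_L,22.02,29.09,30.52,0.00,0.00
Omd_L,28.62,40.63,59.24,0.00,0.00
Osp_L,10.88,32.31,77.81,0.00,0.00
Cal_L,55.53,69.94,63.18,6.59,0.00
Cun_L,7.63,9.40,24.18,0.00,0.00
Lin_L,55.38,100.00,77.67,6.52,0.00
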