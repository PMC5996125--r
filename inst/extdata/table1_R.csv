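region,Tinf_R,TMd_R,TSp_R,Fu_R
Omd_R,0.00,0.00,0.00,0.00
Osp_R,7.77,12.59,11.47,8.54
Cal_R,0.00,0.00,0.00,0.00
Cun_R,5.41,11.83,25.99,0.00
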