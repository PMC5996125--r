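region,Tinf_L,TMd_L,TSp_L,Fu_L
Omd_L,0.00,7.90,26.08,0.00
Osp_L,9.10,41.13,100.00,6.18
Cal_L,0.00,0.00,7.01,0.00
Cun_L,0.00,5.74,33.14,0.00
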