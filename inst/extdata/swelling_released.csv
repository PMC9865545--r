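system,rho_matrix,ta_pct,chdg_pct,q_w,ref_q_v_coll,ref_nu2eq,ref_cp_1e8,ref_delta_c_1e7,ref_dc_1e5
Collagen,1.195,0,0,6.80,7.34,0.136,953,2.5,58
Collagen-TA (5%),1.245,5,0,5.66,6.09,0.164,1150,3.7,103
Collagen-TA (10%),1.290,10,0,4.30,4.61,0.217,1521,6.4,261
Collagen-TA (15%),1.316,15,0,4.11,4.40,0.227,1591,7.0,306
Collagen-TA (5%)-CHDG (9.09%),1.248,5,9.09,4.06,4.35,0.230,1612,7.2,321
Collagen-TA (10%)-CHDG (9.09%),1.285,10,9.09,4.02,4.30,0.233,1633,7.4,336
Collagen-TA (15%)-CHDG (9.09%),1.319,15,9.09,4.16,4.45,0.225,1577,6.9,297
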