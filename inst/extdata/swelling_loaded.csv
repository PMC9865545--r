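system,rho_matrix,ta_pct,chdg_pct,q_w,ref_q_v_matrix,ref_q_v_coll,ref_nu2eq,ref_cp_1e8,ref_delta_c_1e7,ref_dc_1e5
Collagen,1.195,0,0,6.80,7.34,7.34,0.136,953,2.5,58
Collagen-TA (5%),1.245,5,0,5.66,6.31,6.46,0.155,1087,3.3,86
Collagen-TA (10%),1.290,10,0,4.30,4.89,5.11,0.196,1374,5.2,184
Collagen-TA (15%),1.316,15,0,4.11,4.74,5.06,0.198,1388,5.3,191
Collagen-TA (5%)-CHDG (9.09%),1.248,5,9.09,4.06,4.49,4.92,0.203,1423,5.6,208
Collagen-TA (10%)-CHDG (9.09%),1.285,10,9.09,4.02,4.55,5.09,0.196,1374,5.2,184
Collagen-TA (15%)-CHDG (9.09%),1.319,15,9.09,4.16,4.81,5.50,0.182,1276,4.5,144
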