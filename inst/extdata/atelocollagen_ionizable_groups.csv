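name,count,pka_ref,pair_sign,ionization_enthalpy
Asp,90,3.90,-1,4000
Glu,150,4.30,-1,1000
Cterm_Pro,3,3.60,-1,0
His,14,6.00,1,29500
Lys,89,10.50,1,52500
Arg,162,12.50,1,51500
Nterm_Gly,3,8.60,1,45000
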