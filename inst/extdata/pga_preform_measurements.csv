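code,S_l,S_w,S_t,l_w,l_f,l_zt,l_za,l_z,rho_p,C_w_ref,C_f_ref,C_z_ref
3DW-O-ZO,50,28,6.36,51,30,7,6,6.36,0.55,2.00,7.14,10.06
3DW-P-ZO,29,18,6.00,30,20,8,10,3.99,0.73,3.44,11.11,33.33
3DW-P-ZP,36,23,10.00,38,24,15,5,12.50,0.74,5.55,14.28,50.00
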