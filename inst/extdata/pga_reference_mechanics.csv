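code,source,E_11,E_22,E_33,E_p,G_12,G_23,G_13,G_p,nu_12,nu_23,nu_13,nu_p,sigma_11,sigma_22,sigma_33,sigma_ps
3DW-O-ZO,measured,1.30,0.46,0.62,2.38,0.48,0.17,0.23,0.88,0.44,0.45,0.45,0.42,16.04,5.64,7.65,29.29
3DW-P-ZO,measured,1.97,0.63,0.52,3.16,0.73,0.23,0.19,1.17,0.43,0.45,0.45,0.41,24.16,7.78,6.44,38.87
3DW-P-ZP,measured,1.62,0.92,0.65,3.21,0.60,0.34,0.24,1.19,0.43,0.44,0.45,0.40,19.88,11.32,7.98,39.40
3DW-O-ZO,analytical,1.15,0.85,1.19,3.19,0.43,0.32,0.44,1.18,0.44,0.44,0.44,0.40,14.13,10.47,14.65,39.20
3DW-P-ZO,analytical,1.28,0.92,0.21,2.41,0.48,0.34,0.10,0.89,0.44,0.44,0.45,0.42,15.77,11.34,2.57,29.62
3DW-P-ZP,analytical,1.12,0.97,1.39,3.48,0.42,0.36,0.51,1.29,0.44,0.44,0.43,0.40,13.78,11.97,17.05,42.75
3DW-O-ZO,numerical,1.30,0.91,0.46,2.66,0.48,0.34,0.17,0.99,0.44,0.44,0.45,0.41,15.99,11.20,5.61,32.75
3DW-P-ZO,numerical,1.43,0.33,0.46,2.21,0.53,0.12,0.17,0.82,0.43,0.45,0.45,0.42,17.59,4.02,5.61,27.17
3DW-P-ZP,numerical,2.02,0.73,0.33,3.06,0.75,0.27,0.12,1.13,0.42,0.45,0.45,0.41,24.77,8.97,4.02,37.54
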