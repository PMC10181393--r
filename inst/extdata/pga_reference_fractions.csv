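code,source,V_fw,V_ff,V_fz,V_wpr,V_fpr,V_zpr,V_fp,V_tpr
3DW-O-ZO,measured,20.06,7.03,9.55,21.11,21.11,21.11,36.66,63.34
3DW-P-ZO,measured,30.24,9.71,8.03,17.11,17.11,17.11,48.66,51.34
3DW-P-ZP,measured,24.87,14.15,9.96,16.89,16.89,16.89,49.33,50.67
3DW-O-ZO,analytical,17.67,13.09,18.32,16.97,16.97,16.97,49.08,50.92
3DW-P-ZO,analytical,19.72,14.17,3.19,20.97,20.97,20.97,37.08,62.92
3DW-P-ZP,analytical,17.23,14.96,21.33,15.49,15.49,15.49,53.52,46.48
3DW-O-ZO,numerical,20.00,14.00,7.00,19.66,19.66,19.66,41.00,59.00
3DW-P-ZO,numerical,22.00,5.00,7.00,22.66,22.66,22.66,34.00,68.00
3DW-P-ZP,numerical,31.00,11.20,5.00,17.66,17.66,17.66,47.00,53.00
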