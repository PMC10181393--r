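# Full three-architecture comparison using the bundled bench values.
# Measured blocks: bulk density (g/cm^3) plus directional fractions (%).
rho_f: 1.50
voxel:
  enabled: false
  resolution: 40
  cross_section: circle
preforms:
  - code: 3DW-O-ZO
    params: {N: 2, M: 2, T: 2, packing_fraction: 1.0,
             C_w: 0.0200, C_f: 0.0714, C_z: 0.1006}
    measured: {rho_p: 0.55, V_fw: 20.06, V_ff: 7.03, V_fz: 9.55}
  - code: 3DW-P-ZO
    params: {N: 2, M: 2, T: 2, packing_fraction: 1.0,
             C_w: 0.0344, C_f: 0.1111, C_z: 0.3333,
             semi_z_crimp: verbatim}
    measured: {rho_p: 0.73, V_fw: 30.24, V_ff: 9.71, V_fz: 8.03}
  - code: 3DW-P-ZP
    params: {N: 2, M: 2, T: 2, packing_fraction: 1.0,
             C_w: 0.0555, C_f: 0.1428, C_z: 0.5000}
    measured: {rho_p: 0.74, V_fw: 24.87, V_ff: 14.15, V_fz: 9.96}
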