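# Polyglycolic acid (PGA) filament and plied-yarn constants.
filament_diameter_um: 13.7
fiber_density_g_cm3: 1.50    # fiber material density (density -> fraction reduction)
yarn_density_g_cm3: 1.56     # plied-yarn bulk density (effective-diameter derivation)
single_yarn_tex: 6.22
ply_count: 50
linear_density_tex: 311
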