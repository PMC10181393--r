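# Constituent constants for PGA fiber / hydrogel scaffolds.
# G is omitted: it is derived isotropically as E / (2 (1 + nu)).
fiber:
  E_GPa: 6.5
  sigma_MPa: 79.85
  nu: 0.35
matrix:
  E_GPa: 7.5e-5
  sigma_MPa: 2.5e-2
  nu: 0.457
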