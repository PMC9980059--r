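# Pinned atomic constants (version: CODATA-2018 particles, CIAAW-2021
# standard atomic weights, AME-2020 principal isotope masses).
# Units: unified atomic mass (Da); average weights in g/mol.
version: "2021"
average_weight:
  C: 12.011
  H: 1.008
  "N": 14.007
  O: 15.999
  P: 30.973761998
  Na: 22.98976928
monoisotopic_mass:
  C: 12.0
  H: 1.00782503207
  "N": 14.0030740048
  O: 15.9949146196
  P: 30.97376163
  Na: 22.9897692809
particle:
  proton: 1.007276466
  electron: 0.000548579909
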