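# Default ionizable-group pKa table ("EMBOSS" set, as used by the EMBOSS
# iep/pepstats tools). Swappable: pass any table with the same layout to
# netCharge()/isoelectricPoint(). Values in pH units.
name: EMBOSS
n_terminus: 8.6
c_terminus: 3.6
positive:         # protonated form carries +1
  H: 6.5
  K: 10.8
  R: 12.5
negative:         # deprotonated form carries -1
  D: 3.9
  E: 4.1
  C: 8.5
  "Y": 10.1   # quoted: bare Y is YAML-1.1 boolean
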