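# Default degenerate motif definitions used for cGLR active-site curation.
# Syntax: uppercase letter = fixed residue; [ABC] or [A/B] = residue class;
# a bare class letter (declared under `classes`) = named class;
# [Xm-n] = spacer of m..n arbitrary residues (inclusive bounds, counted
# strictly between the flanking anchors).
classes:
  h: [A, C, F, I, L, M, V, W, "Y"]   # hydrophobic (configurable); Y quoted (YAML-1.1 boolean)
patterns:
  active_site: "h[QT]GS[X8-20][DE]h[DE]h[X50-90]h[DE]h"
  activation_loop: "G[SG]"
  catalytic_triad: "[ED]h[ED][X50-90][ED]"
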