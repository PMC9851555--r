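# Diagnostic active-site residues distinguishing Apiaceae flavone synthase I
# (FNS I) from flavanone 3-hydroxylase (F3H). Positions are numbered on the
# Petroselinum crispum FNS I reference (GenBank AAP57393.1). The two
# sufficiency sets are the experimentally established minimal substitution
# sets conferring (partial) FNS I activity on an F3H background
# (M106T+I131F+D195E, and I131F+L215V+K216R).
reference_id: AAP57393.1
positions: [106, 115, 116, 131, 195, 200, 215, 216]
fnsi_residues: [T, T, I, F, E, I, V, R]
f3h_residues: [M, I, V, I, D, V, L, K]
sufficiency_sets:
  - {106: T, 131: F, 195: E}
  - {131: F, 215: V, 216: R}
# Auxiliary site: position 240 in the numbering of the liverwort
# Plagiochasma appendiculatum FNS I/F2H (PaFNSI), where a P/Y contrast
# separates seed-plant F3H from ancestral FNS I lineages. Apiaceae FNS I and
# F3H both retain P here.
aux_position:
  position: 240
  reference_id: PaFNSI
  expected: P
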