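# Default subhaplotype nomenclature for the 17q21.31 tag panel.
#
# Patterns are allele indices (0 = panel REF, 1 = panel ALT) over the six
# subhaplotype-tagging SNVs in panel order:
#   rs1467967 (G>A), rs242557 (G>A), rs3785883 (A>G),
#   rs2471738 (C>T), rs8070723 (A>G), rs7521 (A>G)
# rs8070723-ALT marks the H2 class; all H1-class patterns carry 0 there.
#
# SYNTHETIC / APPROXIMATE: this table is a package-curated approximation of
# the published SNV-based (Pittman-style) nomenclature, reconstructed without
# access to the primary tables. It is intended as a working default and as
# the fixture the simulator inverts; review and edit it for production use.
# Analyses record this file's md5 checksum in their run logs.
#
# The h2_subtypes rules distinguish the CNV-defined H2 subtypes (H2D vs
# H2'/H2.1) among haplotypes already confirmed as H2 by the three-SNV rule
# (rs1052553, rs199451, rs199533 all ALT). The discriminating SNVs used by
# the published CNV-based nomenclature are not in the tag panel; the
# placeholder rules below key on rs1467967 so that the classifier surface is
# exercised end to end. Replace them with the published requirement sets for
# real analyses.
subhaplotypes:
  - {label: H1a, pattern: [0, 0, 0, 0, 0, 0], class: H1}
  - {label: H1b, pattern: [1, 1, 0, 0, 0, 0], class: H1}
  - {label: H1c, pattern: [0, 1, 0, 1, 0, 0], class: H1}
  - {label: H1d, pattern: [1, 0, 1, 0, 0, 0], class: H1}
  - {label: H1e, pattern: [1, 0, 0, 0, 0, 0], class: H1}
  - {label: H1h, pattern: [0, 1, 0, 0, 0, 0], class: H1}
  - {label: H1i, pattern: [1, 0, 0, 1, 0, 0], class: H1}
  - {label: H1j, pattern: [1, 1, 1, 0, 0, 1], class: H1}
  - {label: H1l, pattern: [0, 0, 1, 0, 0, 0], class: H1}
  - {label: H1m, pattern: [1, 0, 0, 0, 0, 1], class: H1}
  - {label: H1o, pattern: [0, 0, 0, 1, 0, 0], class: H1}
  - {label: H1u, pattern: [0, 0, 0, 0, 0, 1], class: H1}
  - {label: H1v, pattern: [1, 1, 0, 0, 0, 1], class: H1}
  - {label: H1x, pattern: [0, 0, 1, 0, 0, 1], class: H1}
  - {label: H1y, pattern: [0, 1, 1, 0, 0, 0], class: H1}
  - {label: H2a, pattern: [0, 0, 0, 0, 1, 0], class: H2}
h2_subtypes:
  - label: H2D
    requirements:
      - {rsid: rs1467967, allele: 0}
  - label: "H2'"
    requirements:
      - {rsid: rs1467967, allele: 1}
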