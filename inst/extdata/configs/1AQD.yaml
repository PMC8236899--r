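# HLA-DR1 (accession 1AQD), class II. The alpha chain (A) carries pa
# (II-alpha-1) and ia (II-alpha-2); the beta chain (B) carries pb
# (II-beta-1) and ib (II-beta-2). The bound endogenous peptide (chain C)
# register anchor p1 names the author residue number of the P1 pocket
# residue; verify against the deposited entry (class II registers come from
# the crystallographic literature, not from this package).
accession: 1AQD
class_label: MHC-II
domains:
  pa: {chain: A, start: 1, end: 84, canon_start: 1}
  ia: {chain: A, start: 85, end: 182, canon_start: 1}
  pb: {chain: B, start: 1, end: 95, canon_start: 1}
  ib: {chain: B, start: 96, end: 190, canon_start: 1}
peptide: {chain: C, p1: 3, omega: 11}
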