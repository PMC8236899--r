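# HLA-A2 (accession 3PWN), class I. Heavy chain A carries the pa (alpha-1),
# pb (alpha-2) and ib (alpha-3) domains under the classic HLA-A2 numbering;
# beta-2-microglobulin (chain B) is the ia domain. The 9-mer peptide in
# chain C runs P1..P9 from its first residue.
accession: 3PWN
class_label: MHC-I
domains:
  pa: {chain: A, start: 1, end: 90, canon_start: 1}
  pb: {chain: A, start: 91, end: 182, canon_start: 1}
  ib: {chain: A, start: 183, end: 276, canon_start: 1}
  ia: {chain: B, start: 1, end: 99, canon_start: 1}
peptide: {chain: C, p1: 1, omega: 9}
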