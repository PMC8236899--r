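# Nurse shark UAA*01 (accession 6LUP), class I; chain roles as in the
# deposited entry (heavy chain A, beta-2-m B, 9-mer peptide C). Domain
# boundaries follow the canonical class I architecture; verify the author
# numbering against the deposited SEQRES before use.
accession: 6LUP
class_label: MHC-I
domains:
  pa: {chain: A, start: 1, end: 90, canon_start: 1}
  pb: {chain: A, start: 91, end: 182, canon_start: 1}
  ib: {chain: A, start: 183, end: 276, canon_start: 1}
  ia: {chain: B, start: 1, end: 98, canon_start: 1}
peptide: {chain: C, p1: 1, omega: 9}
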