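Reference inputs consumed by the acceptance checks are not redistributed
with the package and must be placed here by the user:

  1AQD.pdb, 3PWN.pdb, 6LUP.pdb   coordinate files from the PDB
                                 (https://files.rcsb.org/download/<ID>.pdb)
  sm1_alignment.fasta            curated gapped domain alignment
  sm1_blocks.yaml                its block/group definition

Numbering configurations for the three structures ship under
inst/extdata/configs/.
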