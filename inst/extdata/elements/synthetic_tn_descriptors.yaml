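# Synthetic stand-in descriptors for three Tn3-family transposable elements.
# IR lengths follow the published element geometries (Tn4656 39 bp, Tn5053
# 25 bp, Tn5563 38 bp); the IR and protein sequences themselves are
# synthetic, fixed test sequences, not the real element termini.
proteins_fasta: synthetic_tn_proteins.fasta
families:
  - label: Tn4656-like
    ir: GCTACATGACTGCGCAGAATTGTACCAAAAGTTTGTACC
    proteins:
      - {name: tn4656_tnpA, role: transposase}
      - {name: tn4656_tnpR, role: transposase}
      - {name: tn4656_mcpT, role: cargo}
      - {name: tn4656_istB, role: cargo}
  - label: Tn5053-like
    ir: CTGTGTGCTAGCACTCAACCTTCCG
    proteins:
      - {name: tn5053_tnpA, role: transposase}
      - {name: tn5053_tnpR, role: transposase}
      - {name: tn5053_merR, role: cargo}
      - {name: tn5053_merT, role: cargo}
      - {name: tn5053_merA, role: cargo}
  - label: Tn5563-like
    ir: CTTTCTGTGAGACGACCCCCTGAATGTCCCCCAAGAAG
    proteins:
      - {name: tn5563_tnpA, role: transposase}
      - {name: tn5563_tnpR, role: transposase}
      - {name: tn5563_merP, role: cargo}
      - {name: tn5563_pilT, role: cargo}
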