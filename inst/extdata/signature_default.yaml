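# 20-gene lymph-node metastasis qPCR panel.
# Only eight genes have published directions of regulation in LN+ disease;
# the rest are unspecified and must be set by the user before scoring.
genes:
  - TOX3
  - SLC11A2
  - FAM36A
  - LIMCH1
  - RAB15
  - AVL9
  - PCMTD2
  - PTHLH
  - DPP4
  - PCDHGA10
  - MT1E
  - MAP4K4
  - SLC16A1
  - BST2
  - MMP14
  - IFI27
  - NCLN
  - HLA_G
  - RRBP1
  - ICAM1
direction:
  AVL9: up
  PCMTD2: up
  FAM36A: up
  LIMCH1: up
  RAB15: up
  NCLN: down
  MAP4K4: down
  MMP14: down
housekeeping:
  - ACTB
  - HPRT
reference_genes:
  - ACTB
ct_ceiling: 35
aliases:
  FAM36A: COX20
  HLA_G: HLA G
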