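# Hierarchical phenotyping rules for the default protein panel.
# Modifiers: pos/allpos = all listed markers gated > 0.5; anypos = at
# least one > 0.5; neg = all listed markers gated <= 0.5.
- phenotype: Epithelial
  anypos: [PanCK, CK19]
  neg: [CD45, VIM]
- phenotype: Epi.TAE
  parent: Epithelial
  pos: [CK19]
- phenotype: Epi.OE
  parent: Epithelial
  pos: [CD138]
  neg: [CK19]
- phenotype: Immune
  pos: [CD45]
- phenotype: T
  parent: Immune
  pos: [CD3]
- phenotype: Th
  parent: T
  pos: [CD4]
  neg: [CD8]
- phenotype: Tc
  parent: T
  pos: [CD8]
  neg: [CD4]
- phenotype: B
  parent: Immune
  pos: [CD20]
  neg: [CD3]
- phenotype: Neutrophil
  parent: Immune
  pos: [MPO]
  neg: [CD3, CD20]
- phenotype: Plasma
  parent: Immune
  pos: [CD138]
  neg: [CD3, CD20, MPO]
- phenotype: APC
  parent: Immune
  pos: [HLADR]
  neg: [CD3, CD20, MPO, CD138]
- phenotype: Stromal
  pos: [VIM]
  neg: [CD45, PanCK]
- phenotype: Endothelial
  parent: Stromal
  pos: [CD31]
- phenotype: Fibroblast
  parent: Stromal
  pos: [SMA]
  neg: [CD31]
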