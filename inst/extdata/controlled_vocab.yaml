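# Editable controlled vocabularies. Extend these lists to admit additional
# labels; the package validates against whatever this file contains.
interaction_types:
  - direct
  - secretory
  - indirect
immune_cells:
  - CD4+ T cell
  - CD8+ T cell
  - regulatory T cell
  - gamma-delta T cell
  - B cell
  - natural killer cell
  - NKT cell
  - dendritic cell
  - macrophage
  - monocyte
  - neutrophil
  - eosinophil
  - mast cell
  - myeloid-derived suppressor cell
functional_groups:
  - notch signaling
  - antigen binding
  - neuropeptide
  - hormone
  - growth factor
  - interferon
  - interleukin
  - tumor necrosis factor
  - chemokine
  - cytokine
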