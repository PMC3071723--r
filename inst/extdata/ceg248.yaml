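# CEG-248 reference: 248 core eukaryotic genes in four conservation
# categories (category 1 = least conserved ... category 4 = most conserved).
# Only the category sizes are needed for coverage arithmetic; gene ids are
# generated as synthetic placeholders when absent.
categories:
  category1: 66
  category2: 56
  category3: 61
  category4: 65
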