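categories:
  splicing: [spliceAI_AG, spliceAI_AL, spliceAI_DG, spliceAI_DL]
  conservation: [phyloP, GERP]
directions:
  popMAF: false
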