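# Curation of the C. acetobutylicum ATCC 824 reconstruction (iCac802 ->
# iCac803): reversibility fixes for phosphoglycerate kinase and
# hydrogenase, removal of the formate dehydrogenase absent from the
# genome, addition of pyruvate transport/exchange and of the
# genome-supported glycerol kinase, and replacement of the proton-symport
# ethanol transporter by passive diffusion.
name: iCac803
ops:
  - kind: set_reversibility
    target: R0239
    payload:
      reversible: true
    note: "ATP:3-phospho-D-glycerate 1-phosphotransferase made reversible"
  - kind: set_reversibility
    target: R1563
    payload:
      reversible: true
    note: "hydrogenase made reversible"
  - kind: remove_reaction
    target: R1562
    note: "formate dehydrogenase not found in the genome"
  - kind: add_reaction
    target: pyrt
    payload:
      equation: "pyr_e <=> pyr"
      name: "pyruvate transport"
    note: "pyruvate transport added so pyruvate can serve as carbon source"
  - kind: add_reaction
    target: EX_PYR_e
    payload:
      equation: "pyr_e <=>"
      name: "pyruvate exchange"
    note: "pyruvate exchange reaction"
  - kind: add_reaction
    target: R0426
    payload:
      equation: "glyc + atp --> glyc3p + adp"
      gene_rule: "CAC1321"
      name: "glycerol kinase"
    note: "glycerol kinase (EC 2.7.1.30, locus tag CAC1321) present in genome"
  - kind: replace_reaction
    target: R1708
    payload:
      id: R1708
      equation: "etoh <=> etoh_e"
      name: "ethanol diffusion"
    note: >-
      ethanol transport re-expressed as passive diffusion instead of a
      proton symport
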