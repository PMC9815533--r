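# Cross-feeding reactions added to the full-scale acetogen/solventogen
# community model (for use with the published reconstructions, which must
# be downloaded separately): butyrate uptake and reduction to
# butyraldehyde by the acetogen, and the acetone-to-isopropanol route
# (uptake, alcohol dehydrogenase, export, exchange). Metabolite ids follow
# the community naming scheme: "_ca" marks the acetogen cytosol, "_e" the
# shared extracellular compartment.
name: community_extras
ops:
  - kind: add_reaction
    target: BUTex_au
    payload:
      equation: "but_e <=> but_ca"
      name: "butyrate transport into the acetogen"
    note: "butyrate can be reassimilated by the acetogen"
  - kind: add_reaction
    target: buttobuta
    payload:
      equation: "but_ca + fdxrd_ca + 2 h_ca --> btal_ca + h2o_ca + fdxox_ca"
      name: "aldehyde:ferredoxin oxidoreductase (butyrate -> butyraldehyde)"
    note: "first step of butyrate reduction to butanol in the acetogen"
  - kind: add_reaction
    target: ACETONE_ca
    payload:
      equation: "acetone_e <=> acetone_ca"
      name: "acetone transport into the acetogen"
    note: "acetone produced by the solventogen can enter the acetogen"
  - kind: add_reaction
    target: ISOBIO
    payload:
      equation: "acetone_ca + nadph_ca + h_ca --> ippoh_ca + nadp_ca"
      name: "alcohol dehydrogenase (acetone -> isopropanol)"
    note: "secondary alcohol dehydrogenase of the acetogen"
  - kind: add_reaction
    target: ISOPRO_ca
    payload:
      equation: "ippoh_ca --> ippoh_e"
      name: "isopropanol export"
    note: "isopropanol leaves the acetogen"
  - kind: add_reaction
    target: EX_IPRO_e
    payload:
      equation: "ippoh_e -->"
      name: "isopropanol exchange"
    note: "isopropanol accumulates in the broth"
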