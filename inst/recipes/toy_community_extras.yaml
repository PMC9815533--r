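# Cross-conversion extension of the toy community: a lumped
# butyrate-to-butanol reduction by the acetogen (butyrate + 2 H2 ->
# butanol via aldehyde:ferredoxin oxidoreductase + alcohol dehydrogenase,
# lumped and H2-driven as the toys do not track NAD(P)H in the acetogen)
# plus the butanol exchange.
name: toy_community_extras
ops:
  - kind: add_reaction
    target: BUTOH_ca
    payload:
      equation: "but_e + 2 h2_e --> buoh_e"
      name: "lumped butyrate reduction to butanol (acetogen)"
    note: "butyrate reassimilation by the acetogen, reduced to butanol"
  - kind: add_reaction
    target: EX_buoh_e
    payload:
      equation: "buoh_e -->"
      name: "butanol exchange"
    note: "butanol leaves the system"
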