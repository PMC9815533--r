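# Curation of the C. beijerinckii NCIMB 8052 reconstruction (iCM925 ->
# iCM943). Electron metabolism is rewired from direct ferredoxin:NAD(P)+
# reductases to chemiosmotic energy conservation: the Rnf complex couples
# ferredoxin oxidation to ion translocation and an ATP synthase recovers
# the gradient, with the Nfn complex bifurcating between the NADH, NADPH
# and ferredoxin pools. The genome encodes neither FNR as a standalone
# enzyme. Rnf/Nfn equations follow standard clostridial biochemistry (the
# source curation names the reactions, not their coefficients); the
# translocation stoichiometry (2 ions per ferredoxin at Rnf, 3 ions per
# ATP at the synthase) is an assumption, flagged as such.
name: iCM943
ops:
  - kind: remove_reaction
    target: FDXNRx
    note: >-
      ferredoxin-NAD+ reductase (EC 1.18.1.3) is not found in the genome;
      its flux is carried by the Rnf complex instead
  - kind: remove_reaction
    target: FDXNRy
    note: >-
      the putative ferredoxin-NADP+ reductase corresponds to the
      NADP-binding subunit of the Nfn complex, not a standalone FNR
  - kind: add_reaction
    target: Rnf
    payload:
      equation: "fdxrd + nad + 2 na1 --> fdxox + nadh + 2 na1_e"
      gene_rule: "rnfC and rnfD and rnfG and rnfE and rnfA and rnfB"
      name: "Na+-translocating ferredoxin:NAD+ oxidoreductase complex"
    note: >-
      Rnf complex (EC 7.2.1.2), gene cluster Cbei_2449-Cbei_2454;
      assumed 2 Na+/H+ translocated per ferredoxin oxidized
  - kind: add_reaction
    target: Nfn
    payload:
      equation: "2 nadp + nadh + fdxrd <=> 2 nadph + nad + fdxox"
      gene_rule: "(nfnA1 and nfnB1) or (nfnA2 and nfnB2)"
      name: "electron-bifurcating ferredoxin-dependent transhydrogenase"
    note: >-
      Nfn complex, candidate subunit pairs Cbei_2182/Cbei_2183 or
      Cbei_0661/Cbei_0662
  - kind: replace_reaction
    target: Habc
    payload:
      id: ATPase
      equation: "adp + pi + 3 na1_e --> atp + h2o + 3 na1"
      gene_rule: "atpB and atpE and atpF"
      name: "ATP synthase"
    note: >-
      the ABC-style hydrogen transporter is replaced by the ATP synthase
      that consumes the Rnf-generated gradient (EC 7.1.2.2, cluster
      Cbei_0412-Cbei_0419); assumed 3 ions per ATP
  - kind: rebalance_stoichiometry
    target: DNOR
    payload:
      stoichiometry:
        n2: -1.0
        fdxrd: -8.0
        atp: -16.0
        h2o: -16.0
        nh3: 2.0
        h2: 1.0
        fdxox: 8.0
        adp: 16.0
        pi: 16.0
    note: >-
      reduced ferredoxin:dinitrogen oxidoreductase (ATP-hydrolyzing)
      stoichiometrically balanced to the canonical nitrogenase reaction
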