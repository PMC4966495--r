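# Reference IgG1 cysteine conjugate.
# Chain masses are reduced average masses (all inter-chain cysteines as free
# thiols); back-derived so that light + 1 drug = 23,580.0 Da and
# heavy(G0F) + 3 drugs = 51,630.6 Da. Synthetic reference values.
chains:
  L1: {role: light, reduced_average_mass: 23203.54}
  L2: {role: light, reduced_average_mass: 23203.54}
  H1: {role: heavy, reduced_average_mass: 50501.22}
  H2: {role: heavy, reduced_average_mass: 50501.22}
glycoforms:
  - {name: G0F, delta: 0.0}
  - {name: G1F, delta: 162.14}
drug:
  formula: C23H24N2O3
  average_mass: 376.46
  attachment: thiol-maleimide
bonds:
  - {id: L1-H1, chain_a: L1, chain_b: H1, site_class: LC-HC}
  - {id: L2-H2, chain_a: L2, chain_b: H2, site_class: LC-HC}
  - {id: hinge-1, chain_a: H1, chain_b: H2, site_class: hinge}
  - {id: hinge-2, chain_a: H1, chain_b: H2, site_class: hinge}
symmetry:
  generators:
    - chains: {L1: L2, L2: L1, H1: H2, H2: H1}
      bonds: {L1-H1: L2-H2, L2-H2: L1-H1, hinge-1: hinge-2, hinge-2: hinge-1}
    - chains: {}
      bonds: {hinge-1: hinge-2, hinge-2: hinge-1}
disulfide_decrement: 2.016
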