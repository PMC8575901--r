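# Cofactor registry: per-dialect selectors mapping the named analysis
# targets (P700 Mg pair, FX irons, chlorophyll Mg set, aromatic ring
# sets) to chains / residue numbers, because chain labels and cofactor
# numbering differ between depositions. Human-editable.
#
# Selector kinds:
#   p700: {kind: atoms, atoms: [{chain, resno, atom}, ...]}
#         {kind: closest_pair, max_sep: <A>}   # special pair = closest Mg-Mg
#   fx:   {chain, resno, atoms: [..]}          # explicit residue
#         {resname: SF4, exclude_chains: [..]} # sweep (FX = the non-PsaC cluster)
#   chl:  {resname: [..], atom: MG, branch_overrides | branch_rule: axial}
#   ring_sets: entries with chain + (resno | resname) and a type drawn from
#     phe (6-atom phenyl), trp (9-atom indole), phq (naphthoquinone head:
#     10 fused-ring carbons + 2 carbonyl oxygens, tail excluded), hex
#     (synthetic C1-C6 hexagon), or an explicit atoms: list.

synthetic:
  p700:
    kind: atoms
    atoms:
      - {chain: A, resno: 1, atom: MG}
      - {chain: B, resno: 1, atom: MG}
  fx:
    chain: X
    resno: 1
    atoms: [FE1, FE2, FE3, FE4]
  chl:
    resname: [CLA]
    atom: MG
    default_branch: antenna
    branch_overrides:
      - {chain: A, resno: 1, branch: ET-chain, label: eC-A1}
      - {chain: B, resno: 1, branch: ET-chain, label: eC-B1}
  ring_sets:
    - {name: ring1_a, chain: Q, resno: 1, type: hex, optional: true}
    - {name: ring1_b, chain: Q, resno: 2, type: hex, optional: true}
    - {name: ring2_a, chain: Q, resno: 3, type: hex, optional: true}
    - {name: ring2_b, chain: Q, resno: 4, type: hex, optional: true}
    - {name: ring3_a, chain: Q, resno: 5, type: hex, optional: true}
    - {name: ring3_b, chain: Q, resno: 6, type: hex, optional: true}
    - {name: ring4_a, chain: Q, resno: 7, type: hex, optional: true}
    - {name: ring4_b, chain: Q, resno: 8, type: hex, optional: true}
    - {name: ring5_a, chain: Q, resno: 9, type: hex, optional: true}
    - {name: ring5_b, chain: Q, resno: 10, type: hex, optional: true}
    - {name: ring6_a, chain: Q, resno: 11, type: hex, optional: true}
    - {name: ring6_b, chain: Q, resno: 12, type: hex, optional: true}

# Deposited Photosystem I dialects. The protein residue numbers are the
# deposited numbers; cofactors are selected by residue name so the
# entries survive numbering differences between depositions. PsaC (the
# FA/FB-bearing subunit) is chain C in these entries -- edit per local copy
# if the deposition differs.
1jb0: &deposited
  p700:
    kind: closest_pair
    max_sep: 7.0
  fx:
    resname: SF4
    exclude_chains: [C]
  chl:
    resname: [CLA, CL1, CL2]
    atom: MG
    branch_rule: axial
  ring_sets:
    - {name: PsaA-Phe689, chain: A, resno: 689, type: phe}
    - {name: PsaB-Phe669, chain: B, resno: 669, type: phe}
    - {name: PsaA-Trp697, chain: A, resno: 697, type: trp}
    - {name: PsaB-Trp677, chain: B, resno: 677, type: trp}
    - {name: PsaB-Trp673, chain: B, resno: 673, type: trp}
    - {name: PhQ_A, chain: A, resname: PQN, type: phq}
    - {name: PhQ_B, chain: B, resname: PQN, type: phq}

7m75: *deposited
7m76: *deposited
7m78: *deposited
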