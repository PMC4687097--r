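# KEGG atom-type decision table.
#
# Rules are evaluated top to bottom per atom; the first rule whose
# conditions all hold assigns its code.  Atoms matched by no rule receive
# the flagged fallback type "<Element>?" and are excluded from pattern
# matching.  Supported condition fields:
#   element     - list of element symbols the rule applies to
#   aromatic    - atom is member of an aromatic bond (true/false)
#   ring        - atom is member of any ring
#   degree      - heavy-atom degree (exact)
#   h_min/h_max - implicit hydrogen count bounds
#   dbl_to      - has a double/triple bond to one of these elements
#   carboxyl    - C: bears =O plus a single-bonded O; O: attached to such a C
#   attached_to - has a single-bonded neighbor among these elements
#
# The subset below covers the environments exercised by liver Phase I/II
# chemistry (sp3/sp2/aromatic carbon families, amine/amide/aromatic
# nitrogen, hydroxyl/ether/carbonyl/carboxyl oxygen, sulfur classes and the
# halogen class X).  Additional KEGG codes can be appended without code
# changes.
types:
  - {code: X,   element: ["F", "Cl", "Br", "I"]}
  - {code: C8x, element: ["C"], aromatic: true, h_min: 1}
  - {code: C8y, element: ["C"], aromatic: true, h_max: 0}
  - {code: C6a, element: ["C"], carboxyl: true}
  - {code: C5x, element: ["C"], dbl_to: ["O", "S"], ring: true}
  - {code: C5a, element: ["C"], dbl_to: ["O", "S"], ring: false}
  - {code: C2x, element: ["C"], dbl_to: ["C", "N"], ring: true, h_min: 1}
  - {code: C2y, element: ["C"], dbl_to: ["C", "N"], ring: true, h_max: 0}
  - {code: C2a, element: ["C"], dbl_to: ["C", "N"], degree: 1}
  - {code: C2b, element: ["C"], dbl_to: ["C", "N"], degree: 2}
  - {code: C2c, element: ["C"], dbl_to: ["C", "N"], degree: 3}
  - {code: C1x, element: ["C"], ring: true, degree: 2}
  - {code: C1y, element: ["C"], ring: true, degree: 3}
  - {code: C1z, element: ["C"], ring: true, degree: 4}
  - {code: C1a, element: ["C"], degree: 1}
  - {code: C1b, element: ["C"], degree: 2}
  - {code: C1c, element: ["C"], degree: 3}
  - {code: C1d, element: ["C"], degree: 4}
  - {code: N4x, element: ["N"], aromatic: true, h_min: 1}
  - {code: N4y, element: ["N"], aromatic: true, h_max: 0}
  - {code: N2b, element: ["N"], dbl_to: ["C", "N", "O"]}
  - {code: N1a, element: ["N"], degree: 1}
  - {code: N1b, element: ["N"], degree: 2}
  - {code: N1c, element: ["N"], degree: 3}
  - {code: N1d, element: ["N"], degree: 4}
  - {code: O2x, element: ["O"], ring: true, degree: 2}
  - {code: O6a, element: ["O"], carboxyl: true}
  - {code: O5a, element: ["O"], dbl_to: ["C", "N"]}
  - {code: O3c, element: ["O"], dbl_to: ["S", "P"]}
  - {code: O2a, element: ["O"], degree: 2}
  - {code: O1d, element: ["O"], degree: 1, attached_to: ["S", "P"]}
  - {code: O1a, element: ["O"], degree: 1}
  - {code: S2x, element: ["S"], aromatic: true}
  - {code: S4a, element: ["S"], dbl_to: ["O"]}
  - {code: S2a, element: ["S"], degree: 2}
  - {code: S1a, element: ["S"], degree: 1}
  - {code: P1b, element: ["P"]}
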