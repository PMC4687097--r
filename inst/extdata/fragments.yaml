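# Conjugate fragments grafted by Phase II (and hydroxylation) rules.
# Each fragment lists heavy atoms (element, implicit H), internal bonds
# (1-based local indices, Kekule order) and the local index of the
# attachment atom; the attachment bond to the reaction center is always a
# single bond.  Structures are constitution-only (no stereochemistry).
fragments:
  hydroxyl:
    atoms:
      - {element: "O", h: 1}
    attach: 1
  methyl:
    atoms:
      - {element: "C", h: 3}
    attach: 1
  acetyl:
    atoms:
      - {element: "C", h: 0}
      - {element: "O", h: 0}
      - {element: "C", h: 3}
    bonds:
      - {i: 1, j: 2, order: 2}
      - {i: 1, j: 3, order: 1}
    attach: 1
  sulfo:
    atoms:
      - {element: "S", h: 0}
      - {element: "O", h: 0}
      - {element: "O", h: 0}
      - {element: "O", h: 1}
    bonds:
      - {i: 1, j: 2, order: 2}
      - {i: 1, j: 3, order: 2}
      - {i: 1, j: 4, order: 1}
    attach: 1
  glucuronosyl:
    # beta-D-glucopyranuronosyl: pyranose ring C1'-C2'-C3'-C4'-C5'-O5'
    # with a carboxyl at C5' and hydroxyls at C2'/C3'/C4'; attaches via C1'
    atoms:
      - {element: "C", h: 1}   # 1  C1' (anomeric)
      - {element: "O", h: 0}   # 2  O5' ring
      - {element: "C", h: 1}   # 3  C5'
      - {element: "C", h: 0}   # 4  C6' carboxyl C
      - {element: "O", h: 0}   # 5  C6'=O
      - {element: "O", h: 1}   # 6  C6'-OH
      - {element: "C", h: 1}   # 7  C4'
      - {element: "O", h: 1}   # 8  C4'-OH
      - {element: "C", h: 1}   # 9  C3'
      - {element: "O", h: 1}   # 10 C3'-OH
      - {element: "C", h: 1}   # 11 C2'
      - {element: "O", h: 1}   # 12 C2'-OH
    bonds:
      - {i: 1, j: 2, order: 1}
      - {i: 2, j: 3, order: 1}
      - {i: 3, j: 4, order: 1}
      - {i: 4, j: 5, order: 2}
      - {i: 4, j: 6, order: 1}
      - {i: 3, j: 7, order: 1}
      - {i: 7, j: 8, order: 1}
      - {i: 7, j: 9, order: 1}
      - {i: 9, j: 10, order: 1}
      - {i: 9, j: 11, order: 1}
      - {i: 11, j: 12, order: 1}
      - {i: 11, j: 1, order: 1}
    attach: 1
  glutathionyl:
    # gamma-Glu-Cys-Gly tripeptide attached through the cysteine sulfur
    atoms:
      - {element: "S", h: 0}   # 1  Cys S (attachment)
      - {element: "C", h: 2}   # 2  Cys C-beta
      - {element: "C", h: 1}   # 3  Cys C-alpha
      - {element: "N", h: 1}   # 4  gamma-Glu amide N
      - {element: "C", h: 0}   # 5  gamma-Glu amide C
      - {element: "O", h: 0}   # 6  gamma-Glu amide O
      - {element: "C", h: 2}   # 7  Glu C-gamma
      - {element: "C", h: 2}   # 8  Glu C-beta
      - {element: "C", h: 1}   # 9  Glu C-alpha
      - {element: "N", h: 2}   # 10 Glu alpha amine
      - {element: "C", h: 0}   # 11 Glu carboxyl C
      - {element: "O", h: 0}   # 12 Glu carboxyl =O
      - {element: "O", h: 1}   # 13 Glu carboxyl OH
      - {element: "C", h: 0}   # 14 Cys-Gly amide C
      - {element: "O", h: 0}   # 15 Cys-Gly amide O
      - {element: "N", h: 1}   # 16 Gly N
      - {element: "C", h: 2}   # 17 Gly C-alpha
      - {element: "C", h: 0}   # 18 Gly carboxyl C
      - {element: "O", h: 0}   # 19 Gly carboxyl =O
      - {element: "O", h: 1}   # 20 Gly carboxyl OH
    bonds:
      - {i: 1, j: 2, order: 1}
      - {i: 2, j: 3, order: 1}
      - {i: 3, j: 4, order: 1}
      - {i: 4, j: 5, order: 1}
      - {i: 5, j: 6, order: 2}
      - {i: 5, j: 7, order: 1}
      - {i: 7, j: 8, order: 1}
      - {i: 8, j: 9, order: 1}
      - {i: 9, j: 10, order: 1}
      - {i: 9, j: 11, order: 1}
      - {i: 11, j: 12, order: 2}
      - {i: 11, j: 13, order: 1}
      - {i: 3, j: 14, order: 1}
      - {i: 14, j: 15, order: 2}
      - {i: 14, j: 16, order: 1}
      - {i: 16, j: 17, order: 1}
      - {i: 17, j: 18, order: 1}
      - {i: 18, j: 19, order: 2}
      - {i: 18, j: 20, order: 1}
    attach: 1
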