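[
  {
    "name": "NBA",
    "provenance": "Nile Blue A: ring deformation marker ~600 cm-1 and ring stretching ~1650 cm-1",
    "bands": [
      {"center": 600, "fwhm": 14, "area": 3.0},
      {"center": 1650, "fwhm": 14, "area": 3.0}
    ]
  },
  {
    "name": "NBA_junction",
    "provenance": "Nile Blue A at the trapped-nanoparticle junction: ring stretching observed at ~1645 cm-1",
    "bands": [
      {"center": 600, "fwhm": 14, "area": 3.0},
      {"center": 1645, "fwhm": 14, "area": 3.0}
    ]
  },
  {
    "name": "MB",
    "provenance": "Methylene Blue: C-C ring stretching ~1630 cm-1; no 600 cm-1 marker",
    "bands": [
      {"center": 1630, "fwhm": 14, "area": 3.0}
    ]
  },
  {
    "name": "TYR_plus1",
    "provenance": "tyrosine, fully protonated (+1): nu8a in-plane ring stretch 1620 cm-1, Fermi doublet 830/854 cm-1 with area ratio 1:1",
    "bands": [
      {"center": 830, "fwhm": 10, "area": 2.0},
      {"center": 854, "fwhm": 10, "area": 2.0},
      {"center": 1620, "fwhm": 14, "area": 3.0}
    ]
  },
  {
    "name": "TYR_minus2",
    "provenance": "tyrosine, fully deprotonated (-2): nu8a downshifted to 1602 cm-1, Fermi doublet area ratio 2:1",
    "bands": [
      {"center": 830, "fwhm": 10, "area": 4.0},
      {"center": 854, "fwhm": 10, "area": 2.0},
      {"center": 1602, "fwhm": 14, "area": 3.0}
    ]
  },
  {
    "name": "HIAPP_helix_coil",
    "provenance": "amylin predominant helix-coil monomer: amide I 1656, amide III 1250/1287, CH2 1450, Phe 1006/1585, Tyr 1605 and doublet 1:1, disulfide g-g-t 523 cm-1",
    "bands": [
      {"center": 523, "fwhm": 14, "area": 1.6},
      {"center": 830, "fwhm": 10, "area": 1.6},
      {"center": 854, "fwhm": 10, "area": 1.6},
      {"center": 1006, "fwhm": 8, "area": 1.2},
      {"center": 1250, "fwhm": 16, "area": 1.6},
      {"center": 1287, "fwhm": 16, "area": 1.3},
      {"center": 1450, "fwhm": 16, "area": 1.6},
      {"center": 1585, "fwhm": 12, "area": 0.8},
      {"center": 1605, "fwhm": 12, "area": 0.8},
      {"center": 1656, "fwhm": 14, "area": 3.0}
    ]
  },
  {
    "name": "HIAPP_typeI",
    "provenance": "amylin type I transient species: broad amide I 1668 cm-1 (turn), doublet 1:1, intact disulfide 523 cm-1",
    "bands": [
      {"center": 523, "fwhm": 14, "area": 1.6},
      {"center": 830, "fwhm": 10, "area": 1.6},
      {"center": 854, "fwhm": 10, "area": 1.6},
      {"center": 1006, "fwhm": 8, "area": 1.2},
      {"center": 1250, "fwhm": 16, "area": 1.6},
      {"center": 1450, "fwhm": 16, "area": 1.6},
      {"center": 1585, "fwhm": 12, "area": 0.8},
      {"center": 1605, "fwhm": 12, "area": 0.8},
      {"center": 1668, "fwhm": 28, "area": 6.0}
    ]
  },
  {
    "name": "HIAPP_typeII",
    "provenance": "amylin type II transient species: amide I 1655 + 1674 cm-1 (helix-coil with beta-sheet), doublet ratio 1.5, intact disulfide 523 cm-1",
    "bands": [
      {"center": 523, "fwhm": 14, "area": 1.6},
      {"center": 830, "fwhm": 10, "area": 1.8},
      {"center": 854, "fwhm": 10, "area": 1.2},
      {"center": 1006, "fwhm": 8, "area": 1.2},
      {"center": 1250, "fwhm": 16, "area": 1.2},
      {"center": 1287, "fwhm": 16, "area": 1.0},
      {"center": 1450, "fwhm": 16, "area": 1.6},
      {"center": 1585, "fwhm": 12, "area": 0.8},
      {"center": 1655, "fwhm": 14, "area": 2.5},
      {"center": 1674, "fwhm": 14, "area": 2.5}
    ]
  },
  {
    "name": "HIAPP_fibril",
    "provenance": "amylin amyloid fibril: amide I 1674, amide III 1226 cm-1 (beta-sheet), strained disulfide 490 cm-1",
    "bands": [
      {"center": 490, "fwhm": 14, "area": 1.6},
      {"center": 830, "fwhm": 10, "area": 1.4},
      {"center": 854, "fwhm": 10, "area": 1.4},
      {"center": 1006, "fwhm": 8, "area": 1.2},
      {"center": 1226, "fwhm": 16, "area": 2.0},
      {"center": 1450, "fwhm": 16, "area": 1.4},
      {"center": 1674, "fwhm": 14, "area": 3.0}
    ]
  }
]
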