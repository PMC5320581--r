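# Default carbohydrate-set map: family-level assignments for CAZy
# families with one canonical substrate; EC-level assignments for
# heterogeneous families. Edit freely; read with read_carb_set_map().
family_sets:
  GH13: Alpha-glucans
  GH31: Alpha-glucans
  GH77: Alpha-glucans
  GH15: Alpha-glucans
  GH32: Fructans
  GH10: Xylans and Arabinans
  GH39: Xylans and Arabinans
  GH43: Xylans and Arabinans
  GH51: Xylans and Arabinans
  GH115: Xylans and Arabinans
  GH120: Xylans and Arabinans
  GH127: Xylans and Arabinans
  GH8: Xylans and Arabinans
  GH28: Pectins
  GH26: Beta-mannans
  GH113: Beta-mannans
  GH130: Beta-mannans
  GH36: Alpha- and Beta-galactosides
  GH29: Host glycans
  GH20: Host glycans
  GH33: Host glycans
  GH38: Host glycans
  GH85: Host glycans
  GH125: Host glycans
  GH53: Type-1 Arabinogalactans
ec_sets:
  3.2.1.89: Type-1 Arabinogalactans
  3.2.1.78: Beta-mannans
  3.2.1.37: Xylans and Arabinans
  3.2.1.55: Xylans and Arabinans
  3.2.1.8: Xylans and Arabinans
  3.2.1.156: Xylans and Arabinans
  3.2.1.15: Pectins
  3.2.1.26: Fructans
  3.2.1.80: Fructans
  3.2.1.1: Alpha-glucans
  3.2.1.41: Alpha-glucans
  3.2.1.135: Alpha-glucans
  3.2.1.10: Alpha-glucans
  3.2.1.20: Alpha-glucans
  3.2.1.18: Host glycans
  3.2.1.22: Alpha- and Beta-galactosides
  3.2.1.23: Alpha- and Beta-galactosides
t1ag_set: Type-1 Arabinogalactans
t1ag_excluded:
  - Xylans and Arabinans
  - Pectins
  - Alpha- and Beta-galactosides
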