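{
  "metabolites": ["A", "B", "C"],
  "reactions": [
    {"id": "EX_A", "stoich": {"A": 1}, "reversible": false, "pathway": "uptake"},
    {"id": "R_AB", "stoich": {"A": -1, "B": 1}, "reversible": false, "pathway": "chain"},
    {"id": "R_BC", "stoich": {"B": -1, "C": 1}, "reversible": true, "pathway": "chain"},
    {"id": "GROWTH", "stoich": {"C": -1}, "reversible": false, "pathway": "biomass"}
  ],
  "objective": "GROWTH"
}
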