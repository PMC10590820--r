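{
  "metabolites": [
    {"id": "A_c", "formula": "C3H6O3", "compartment": "c"},
    {"id": "B_c", "formula": "C3H4O3", "compartment": "c"}
  ],
  "reactions": [
    {
      "id": "EX_A",
      "metabolites": {"A_c": -1},
      "lower_bound": -10,
      "upper_bound": 1000,
      "subsystem": "Exchange/demand",
      "gene_reaction_rule": ""
    },
    {
      "id": "R1",
      "metabolites": {"A_c": -1, "B_c": 1},
      "lower_bound": 0,
      "upper_bound": 1000,
      "subsystem": "Core",
      "gene_reaction_rule": "g1 and (g2 or g3)"
    },
    {
      "id": "EX_B",
      "metabolites": {"B_c": -1},
      "lower_bound": 0,
      "upper_bound": 1000,
      "subsystem": "Exchange/demand",
      "gene_reaction_rule": ""
    }
  ],
  "genes": [{"id": "g1"}, {"id": "g2"}, {"id": "g3"}]
}
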