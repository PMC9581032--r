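{
  "id": "toy_bigg",
  "metabolites": [
    {"id": "C1"},
    {"id": "C2"},
    {"id": "C3"},
    {"id": "C4"}
  ],
  "reactions": [
    {"id": "R1", "metabolites": {"C1": 1}, "lower_bound": 3, "upper_bound": 3},
    {"id": "R2", "metabolites": {"C1": -1, "C2": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "R3", "metabolites": {"C1": -1, "C3": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "R4", "metabolites": {"C2": -1, "C4": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "R5", "metabolites": {"C4": -1, "C3": 1}, "lower_bound": 0, "upper_bound": 1},
    {"id": "R6", "metabolites": {"C3": -1}, "lower_bound": 0, "upper_bound": 1000, "objective_coefficient": 1},
    {"id": "R7", "metabolites": {"C4": -1}, "lower_bound": 0, "upper_bound": 1000}
  ],
  "genes": []
}
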