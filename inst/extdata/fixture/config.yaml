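seed: 101
inputs:
  compounds: compounds.csv
  descriptors: descriptors.csv
  admet: admet.csv
  predictions:
  - tool_id: sim_tool_1
    path: predictions_sim_tool_1.tsv
    covered_targets:
    - P05067
    - P22303
    - P42574
  - tool_id: sim_tool_2
    path: predictions_sim_tool_2.tsv
    covered_targets:
    - P05067
    - P22303
    - P42574
  - tool_id: sim_tool_3
    path: predictions_sim_tool_3.tsv
    covered_targets:
    - P05067
    - P22303
    - P42574
  - tool_id: sim_tool_4
    path: predictions_sim_tool_4.tsv
    covered_targets:
    - P05067
    - P22303
    - P42574
  - tool_id: sim_tool_5
    path: predictions_sim_tool_5.tsv
    covered_targets:
    - P05067
    - P22303
    - P42574
  - tool_id: sim_tool_6
    path: predictions_sim_tool_6.tsv
    covered_targets:
    - P05067
    - P22303
    - P42574
filters:
  excluded_classes:
  - triacylglycerol
  - diacylglycerol
  - phosphatidylethanolamine
  min_mw: 100.0
scoring:
  top_k: 10
targets:
  of_interest:
  - P05067
  - P22303
  - P42574
  top_k: 20
  min_votes: 1
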