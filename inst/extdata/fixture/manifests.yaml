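- tool_id: sim_tool_1
  covered_targets:
  - P05067
  - P22303
  - P42574
- tool_id: sim_tool_2
  covered_targets:
  - P05067
  - P22303
  - P42574
- tool_id: sim_tool_3
  covered_targets:
  - P05067
  - P22303
  - P42574
- tool_id: sim_tool_4
  covered_targets:
  - P05067
  - P22303
  - P42574
- tool_id: sim_tool_5
  covered_targets:
  - P05067
  - P22303
  - P42574
- tool_id: sim_tool_6
  covered_targets:
  - P05067
  - P22303
  - P42574
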