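{
  "_comment": "SYNTHETIC item-to-dimension template, NOT the published instrument's assignment. Replace with your licensed map.",
  "competence": ["core_01", "core_02", "core_03"],
  "sensory_imaginative_immersion": ["core_04", "core_05", "core_06"],
  "flow": ["core_07", "core_08", "core_09"],
  "tension_annoyance": ["core_10", "core_11", "core_12"],
  "challenge": ["core_13", "core_14", "core_15"],
  "negative_affect": ["core_16", "core_17", "core_18"],
  "positive_affect": ["core_19", "core_20", "core_21"],
  "psych_involvement_empathy": ["sp_01", "sp_02", "sp_03"],
  "psych_involvement_negative": ["sp_04", "sp_05", "sp_06"],
  "behavioral_involvement": ["sp_07", "sp_08", "sp_09"]
}
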