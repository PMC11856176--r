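# Synthetic case-calibrated stand-in (after Shin et al.): cumulative hours
# to stage entry at 28.9 degC; egg->L1 20 h, L1->L2 22 h, L2->L3 41 h
# (total 83 h = 3 d 11 h to third instar).
species: Lucilia sericata
base_temp_C: 10
provenance: >-
  Synthetic stand-in calibrated to L. sericata development at 28.9 degC
  (after Shin et al. constant-temperature rearing data)
constant_table:
  - {temp_C: 28.9, stage: instar1, cumulative_hours: 20}
  - {temp_C: 28.9, stage: instar2, cumulative_hours: 42}
  - {temp_C: 28.9, stage: instar3, cumulative_hours: 83}
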