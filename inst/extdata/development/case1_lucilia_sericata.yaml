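# Synthetic case-calibrated stand-in for published constant-temperature
# development of Lucilia sericata (after Shin et al.); cumulative hours to
# stage entry at the case's corrected mean of 26.2 degC, reconstructed from
# the printed stage-boundary timestamps.
species: Lucilia sericata
base_temp_C: 10
provenance: >-
  Synthetic stand-in calibrated to L. sericata development at 26.2 degC
  (after Shin et al. constant-temperature rearing data)
constant_table:
  - {temp_C: 26.2, stage: instar1, cumulative_hours: 24}
  - {temp_C: 26.2, stage: instar2, cumulative_hours: 47}
  - {temp_C: 26.2, stage: instar3, cumulative_hours: 95}
  - {temp_C: 26.2, stage: post_feeding, cumulative_hours: 166}
  - {temp_C: 26.2, stage: puparium, cumulative_hours: 243}
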