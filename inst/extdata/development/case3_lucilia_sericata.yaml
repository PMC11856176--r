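# Synthetic case-calibrated stand-in (after Shin et al.): cumulative hours
# to stage entry at 21.6 degC, reconstructed from the printed
# stage-boundary timestamps (336 h = 14 d to puparium).
species: Lucilia sericata
base_temp_C: 10
provenance: >-
  Synthetic stand-in calibrated to L. sericata development at 21.6 degC
  (after Shin et al. constant-temperature rearing data)
constant_table:
  - {temp_C: 21.6, stage: instar1, cumulative_hours: 35}
  - {temp_C: 21.6, stage: instar2, cumulative_hours: 70}
  - {temp_C: 21.6, stage: instar3, cumulative_hours: 145}
  - {temp_C: 21.6, stage: post_feeding, cumulative_hours: 254}
  - {temp_C: 21.6, stage: puparium, cumulative_hours: 336}
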