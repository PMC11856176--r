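# Synthetic case-calibrated stand-in (after Zhang et al.): 185 h
# (7 d 17 h) from oviposition to puparium at 21.6 degC.
species: Chrysomya megacephala
base_temp_C: 10
provenance: >-
  Synthetic stand-in calibrated to C. megacephala development at 21.6 degC
  (after Zhang et al. constant-temperature rearing data)
constant_table:
  - {temp_C: 21.6, stage: puparium, cumulative_hours: 185}
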