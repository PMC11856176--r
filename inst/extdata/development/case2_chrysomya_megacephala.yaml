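# Synthetic case-calibrated stand-in (after Zhang et al.): 46 h
# (1 d 22 h) from oviposition to third instar at 28.9 degC.
species: Chrysomya megacephala
base_temp_C: 10
provenance: >-
  Synthetic stand-in calibrated to C. megacephala development at 28.9 degC
  (after Zhang et al. constant-temperature rearing data)
constant_table:
  - {temp_C: 28.9, stage: instar3, cumulative_hours: 46}
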