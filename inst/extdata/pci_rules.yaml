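# Minimum pre-colonization intervals by species and ambient-temperature band.
rules:
  - species: Lucilia sericata
    temp_range_C: [14.0, 25.1]
    min_pci_days: 0.2
    provenance: Matuszewski et al., minimum PCI for adult L. sericata
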