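{
  "case_id": "busan-2022-case2",
  "discovery_time": "2022-08-12 14:50",
  "collection_time": "2022-08-12 14:50",
  "location_class": "indoor",
  "specimens": [
    {"sample_id": "Case 2-1", "species": "C. megacephala", "stage": "instar3", "sequence_length_bp": 804, "accession": "MK075787.1", "identity_pct": 98},
    {"sample_id": "Case 2-2", "species": "C. megacephala", "stage": "instar3", "sequence_length_bp": 1200, "accession": "MK075787.1", "identity_pct": 99},
    {"sample_id": "Case 2-3", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 794, "accession": "JX913756.1", "identity_pct": 99},
    {"sample_id": "Case 2-4", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 804, "accession": "JX913756.1", "identity_pct": 99},
    {"sample_id": "Case 2-5", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 801, "accession": "KT272854.1", "identity_pct": 99},
    {"sample_id": "Case 2-6", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 1232, "accession": "KT272854.1", "identity_pct": 99},
    {"sample_id": "Case 2-7", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 797, "accession": "KT272854.1", "identity_pct": 99},
    {"sample_id": "Case 2-8", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 1181, "accession": "KT272854.1", "identity_pct": 99}
  ],
  "last_known_activity": "2022-08-07",
  "reference_granularity": "day",
  "corrected_mean_temp_C": 28.9,
  "notes": [
    "Discovery clock time 14:50 per the case narrative (a summary table elsewhere rounds it to 14h00); the finer value is used.",
    "Last known activity is a phone call dated 7 August 2022 (date only)."
  ]
}
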