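{
  "case_id": "busan-2022-case3",
  "discovery_time": "2022-09-30 11:50",
  "collection_time": "2022-09-30 11:50",
  "location_class": "indoor",
  "specimens": [
    {"sample_id": "Case 3-1", "species": "L. sericata", "stage": "puparium", "sequence_length_bp": 899, "accession": "JX913756.1", "identity_pct": 99},
    {"sample_id": "Case 3-2", "species": "L. sericata", "stage": "puparium", "sequence_length_bp": 891, "accession": "JX913756.1", "identity_pct": 99},
    {"sample_id": "Case 3-3", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 832, "accession": "JX913756.1", "identity_pct": 98},
    {"sample_id": "Case 3-4", "species": "L. sericata", "stage": "instar3", "sequence_length_bp": 1336, "accession": "JX913756.1", "identity_pct": 99},
    {"sample_id": "Case 3-5", "species": "C. megacephala", "stage": "puparium", "sequence_length_bp": 1228, "accession": "MK075810.1", "identity_pct": 99},
    {"sample_id": "Case 3-6", "species": "C. megacephala", "stage": "puparium", "sequence_length_bp": 1213, "accession": "MH778895.1", "identity_pct": 99},
    {"sample_id": "Case 3-7", "species": "C. megacephala", "stage": "instar3", "sequence_length_bp": 1156, "accession": "MK075780.1", "identity_pct": 98},
    {"sample_id": "Case 3-8", "species": "C. megacephala", "stage": "instar3", "sequence_length_bp": 1184, "accession": "MK075780.1", "identity_pct": 99}
  ],
  "last_known_activity": "2022-09-15",
  "reference_granularity": "day",
  "corrected_mean_temp_C": 21.6,
  "notes": [
    "Medical-examiner estimate of death: 15 September 2022 (date only).",
    "Published stage intervals sum to 14 d 0 h although the narrative total reads 'approximately 14 days and 8 h'; the development law shipped with this case is calibrated to the printed stage-boundary timestamps (336 h total)."
  ]
}
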