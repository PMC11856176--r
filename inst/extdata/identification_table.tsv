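sample_id	sequence_length_bp	species	accession	identity_pct
Case 1-1	794	L. sericata	JX913756.1	99
Case 1-2	1232	L. sericata	JX913756.1	99
Case 1-3	792	L. sericata	JX913756.1	99
Case 1-4	1359	L. sericata	JX913756.1	99
Case 1-5	786	L. sericata	JX913756.1	98
Case 1-6	823	L. sericata	JX913756.1	100
Case 1-7	952	L. sericata	JX913756.1	99
Case 1-8	966	L. sericata	JX913756.1	100
Case 2-1	804	C. megacephala	MK075787.1	98
Case 2-2	1200	C. megacephala	MK075787.1	99
Case 2-3	794	L. sericata	JX913756.1	99
Case 2-4	804	L. sericata	JX913756.1	99
Case 2-5	801	L. sericata	KT272854.1	99
Case 2-6	1232	L. sericata	KT272854.1	99
Case 2-7	797	L. sericata	KT272854.1	99
Case 2-8	1181	L. sericata	KT272854.1	99
Case 3-1	899	L. sericata	JX913756.1	99
Case 3-2	891	L. sericata	JX913756.1	99
Case 3-3	832	L. sericata	JX913756.1	98
Case 3-4	1336	L. sericata	JX913756.1	99
Case 3-5	1228	C. megacephala	MK075810.1	99
Case 3-6	1213	C. megacephala	MH778895.1	99
Case 3-7	1156	C. megacephala	MK075780.1	98
Case 3-8	1184	C. megacephala	MK075780.1	99
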