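genome_id	orphan	pair	triad	tetrad	pentad	total_tcs	group
Leptodesmis_A121	92	12	5	0	0	131	thermophile
Leptolyngbya_JSC-1	137	35	9	0	1	239	thermophile
Leptothermofonsia_E412	120	17	4	1	1	175	thermophile
Thermoleptolyngbya_A183	91	8	1	0	1	115	thermophile
Thermoleptolyngbya_O-77	84	14	1	0	1	120	thermophile
Thermostichus_60AY4M2	46	1	1	0	0	51	thermophile
Thermostichus_63AY4M2	46	1	1	0	0	51	thermophile
Thermostichus_65AY6A5	46	1	1	0	0	51	thermophile
Thermostichus_65AY6Li	44	2	1	0	0	51	thermophile
Thermostichus_JA-2-3Ba	39	3	2	0	0	51	thermophile
Thermostichus_JA-3-3Ab	42	3	1	0	0	51	thermophile
Thermosynechococcus_PCC6715	42	2	1	0	0	49	thermophile
Thermosynechococcus_CL-1	33	7	0	0	0	47	thermophile
Thermosynechococcus_TA-1	35	6	0	0	0	47	thermophile
Thermosynechococcus_BP-1	32	5	0	0	0	42	thermophile
Thermosynechococcus_E542	38	3	0	0	0	44	thermophile
Thermosynechococcus_NIES-2134	36	3	0	0	0	42	thermophile
Cylindrospermum_PCC7417	107	27	3	1	0	174	reference
Microcystis_NIES-843	41	2	0	0	0	45	reference
Nostoc_PCC7524	109	25	4	0	0	171	reference
Parasynechococcus_WH7803	19	2	1	0	0	26	reference
Synechocystis_PCC6803	70	10	0	0	0	90	reference
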