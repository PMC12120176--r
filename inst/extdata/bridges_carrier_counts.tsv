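stratum	n_variants	carriers_cases	carriers_controls	total_cases	total_controls
AM_ge_0.75	33	94	18	53572	48048
AM_0.65_to_0.75	7	22	16	53572	48048
AM_le_0.65	82	146	101	53572	48048
DDG_AF_ge_2.5	32	97	20	53572	48048
DDG_AF_1.5_to_2.5	23	43	24	53572	48048
DDG_AF_le_1.5	67	122	91	53572	48048
DDG_PDB_ge_2.5	35	121	30	53572	48048
DDG_PDB_1.5_to_2.5	19	16	15	53572	48048
DDG_PDB_le_1.5	68	125	90	53572	48048
BD_ge_0.28	33	120	30	53572	48048
BD_0.15_to_0.28	19	54	30	53572	48048
BD_le_0.15	70	88	75	53572	48048
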