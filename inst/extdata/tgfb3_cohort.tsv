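# Reconstructed 27-carrier cohort table. Published totals (cohort size,
# sex split, per-category counts, selected ages and aortic Z-scores) are
# reproduced; the per-individual flag assignment is SYNTHETIC, composed to
# be consistent with the published family narratives. reported_z carries
# published aortic Z-scores as annotation only (never computed here).
family_id	individual_id	sex	age	taad	arterial_other	cardio_other	connective	reported_z
FAM1	F1-II4	male	77	0	0	1	1	NA
FAM1	F1-II8	male	64	0	0	1	1	NA
FAM1	F1-III5	male	49	0	0	1	1	NA
FAM1	F1-III9	male	36	0	0	0	1	2.0
FAM1	F1-III2	male	45	0	0	1	1	NA
FAM1	F1-III7	male	41	0	0	1	1	NA
FAM1	F1-II6	female	71	0	1	0	1	NA
FAM1	F1-III11	male	29	0	0	0	1	NA
FAM1	F1-IV1	male	7	0	0	0	0	NA
FAM1	F1-IV2	female	12	0	0	0	0	NA
FAM2	F2-II8	male	74	1	0	1	1	5.2
FAM2	F2-II2	male	80	1	0	1	0	2.1
FAM2	F2-II5	female	55	0	0	1	1	NA
FAM2	F2-III4	female	44	0	0	0	0	NA
FAM2	F2-III5	female	41	0	0	0	0	1.7
FAM2	F2-IV2	male	18	0	0	0	0	NA
FAM3	F3-II1	male	15	0	0	0	1	0.0
FAM4	F4-III6	male	31	1	0	0	0	NA
FAM4	F4-II1	female	76	0	0	0	0	NA
FAM4	F4-II3	male	70	0	0	0	0	NA
FAM4	F4-III2	female	48	0	0	0	0	NA
FAM4	F4-III4	female	44	0	0	0	0	NA
FAM4	F4-IV1	male	19	0	0	0	0	NA
FAM4	F4-IV3	female	5	0	0	0	0	NA
FAM5	F5-II1	male	75	1	0	0	1	6.4
FAM5	F5-III2	female	50	0	0	1	1	NA
FAM5	F5-IV1	male	25	0	0	0	1	NA
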