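# Reconstructed genotypes of the six genotyped carriers (five families; one
# family contributed two individuals). Allele sizes are SYNTHETIC fragment
# sizes chosen to reproduce the published per-marker sharing pattern:
# shared at D14S1065, D14S258, D14S1047, D14S61, D14S270; discordant
# elsewhere. columns: family individual carrier then 2 alleles per marker
# in map order.
FAM1	F1-II8	1	150	152	162	164	180	182	144	146	210	212	196	198	170	172	220	222	156	158	240	242	130	132
FAM1	F1-III5	1	150	154	162	162	180	184	144	148	210	214	196	196	170	174	220	224	156	160	240	244	130	134
FAM2	F2-II8	1	150	150	162	166	182	184	144	144	210	210	196	200	172	174	222	224	158	160	242	244	132	134
FAM3	F3-II1	1	150	152	162	164	186	188	144	146	210	216	196	198	176	178	226	228	162	164	246	248	136	138
FAM4	F4-III6	1	150	156	162	168	186	190	144	150	210	212	196	202	176	180	226	230	162	166	246	250	136	140
FAM5	F5-III2	1	150	152	162	162	188	190	144	148	210	214	196	196	178	180	228	230	164	166	248	250	138	140
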