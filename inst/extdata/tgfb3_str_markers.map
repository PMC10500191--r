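# Reconstructed STR marker map for the TGFB3 p.(Asp263His) founder panel.
# Marker names and order match the published panel; cM/bp coordinates are
# SYNTHETIC stand-ins chosen to reproduce the published span sizes
# (minimal D14S1047-D14S270: 2.13 cM / 1.92 Mb; maximal D14S1028-D14S983:
# 6.54 cM / 4.14 Mb). They are not Marshfield/GRCh37 positions.
# columns: chromosome name pos_cM pos_bp het ('*' flags the focal variant)
14	D14S1065	74.00	71800000	0.63
14	D14S258	76.50	73200000	0.65
14	D14S1028	78.00	74300000	0.67
14	D14S1047	79.80	75500000	0.69
14	D14S61	80.50	76100000	0.71
14*	TGFB3_c787GC	80.90	76446000	NA
14	D14S270	81.93	77420000	0.73
14	D14S983	84.54	78440000	0.75
14	D14S74	86.00	79600000	0.77
14	D14S287	88.20	81000000	0.79
14	D14S1037	90.10	82500000	0.81
14	D14S1044	92.00	84000000	0.83
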