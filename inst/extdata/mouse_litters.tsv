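# Mouse sperm-mutagenesis litters: four double-transgenic seed males, 12 litters.
# n_pcr_positive = transposon-PCR-positive pups; n_new_insertion = PCR positives
# carrying a new (non-founder) insertion; n_gfp_positive = visibly GFP-positive pups.
library	litter	n_pups	n_pcr_positive	n_new_insertion	n_gfp_positive
TnE2/Tp62	1	8	4	1	0
TnE2/Tp62	2	9	3	2	0
TnE2/Tp62	3	11	5	1	1
TnE2/Tp191	1	15	11	1	0
TnE2/Tp191	2	9	3	0	0
TnE2/Tp191	3	15	10	1	0
TnE2/Tp68	1	13	9	1	0
TnE2/Tp68	2	10	6	1	0
TnE2/Tp68	3	13	7	0	0
TnE2/Tp64	1	12	5	1	1
TnE2/Tp64	2	13	6	1	1
TnE2/Tp64	3	7	3	1	0
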