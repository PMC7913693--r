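# Germline mobilization events of the ZB enhancer-trap transposon in mice.
# role "origin" marks the founder insertion (TnE2); "event" rows are
# re-transposition events recovered from F1 pups. Junction sequences read
# [genomic flank][TA][start of the transposon TIR]; the TIR start is
# "cagcgggga". Loci are 1-based points on GRCm38/mm10. orientation is
# carried verbatim (F/R, N = not applicable); distance rendering for
# different-chromosome events is "-".
role	line	junction_sequence	chrom	pos	nearest_gene	compartment	orientation	gfp
origin	TnE2	aggttccaggaacaTAcagcgggga	Chr13	102860981	Mast4	intron	F	FALSE
event	nl1	cctccacaggttcaTAcagcgggga	Chr13	55978551	NA	intergenic	N	FALSE
event	nl1a	atactatctaccatgttataTAcagcgggga	Chr16	44756211	Nepro	exon	F	FALSE
event	nl2	attttacatgtgtaTAcagcgggga	Chr16	76050830	NA	intergenic	N	FALSE
event	nl3	gatgttacctattggctttcTAcagcgggga	Chr4	67355475	NA	intergenic	N	FALSE
event	nl5	aaaacgacagcacaTAcagcgggga	Chr13	102860624	Mast4	intron	R	TRUE
event	nl5a	agtcacatggagtagcTAcagcgggga	Chr13	102860526	Mast4	intron	F	FALSE
event	nl9	ccagagtactgtgaTAcagcgggga	Chr13	102925178	Mast4	intron	R	TRUE
event	nl11	gcaagtgttatacaTAcagcgggga	Chr11	101962858	Sost	exon	R	TRUE
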