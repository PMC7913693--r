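# Transgenic founder generation by pronuclear injection:
# transposase line (ZBase, SB-vector-mediated) and enhancer-trap line
# (ZB-vector-mediated). n_transgenic of n_born pups carried the transgene.
cohort	n_transgenic	n_born
zbase_transposase	20	28
zb_enhancer_trap	5	36
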