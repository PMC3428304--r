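# Modification increments on the unmodified (free-thiol, non-oxidized) peptide.
# sign: +1 the formula is added, -1 it is removed.
name	delta_formula	sign	note
prenyl	C5H8	1	heteroatom-bound dimethylallyl (isoprenoid, nominal +68)
geranyl	C10H16	1	heteroatom-bound geranyl (two isoprenoid units, nominal +136)
disulfide	H2	-1	intramolecular Cys-Cys bridge (oxidative loss of two H)
met_sulfoxide	O	1	methionine sulfoxide, sample-preparation artifact (nominal +16)
cam_cys	C2H3NO	1	carboxyamidomethyl on one free cysteine thiol (iodoacetamide)
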