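te_id	family	nearby_gene	te_location	gene_is_hub	gene_direction	single_te	selection_evidence	cnc_bs	atac_peak
FBti0019170	F-element	kuz	inside_gene	TRUE	NA	TRUE	fTE	0	FALSE
FBti0019372	S-element	rdx	inside_gene	TRUE	NA	TRUE	H12	1	FALSE
FBti0019082	Rt1b	CR6900	five_prime	TRUE	NA	TRUE	TajimaD	3	TRUE
FBti0020393	1360	cindr	inside_gene	TRUE	NA	TRUE	TajimaD	0	FALSE
FBti0020329	G5	Mrp4	five_prime	TRUE	NA	TRUE	TajimaD	0	FALSE
FBti0062283	ninja-Dsim-like	Arpc3B	five_prime	TRUE	NA	TRUE	TajimaD	0	FALSE
FBti0020015	412	LysS	five_prime	TRUE	NA	TRUE	young_and_long	3	FALSE
FBti0015567	Tirant	Fs(2)Ket	inside_gene	TRUE	NA	TRUE	none	1	FALSE
FBti0020137	S-element	CG5589	three_prime	TRUE	NA	TRUE	none	1	FALSE
FBti0062779	1360	La	five_prime	TRUE	NA	TRUE	none	0	TRUE
FBti0061088	INE-1	Ag5r2	five_prime	TRUE	NA	TRUE	none	0	TRUE
FBti0064264	INE-1	Holn1	three_prime	TRUE	NA	TRUE	none	0	TRUE
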