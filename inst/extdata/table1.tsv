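sample_id	who_classification	histology	genetic_subtype	idh1_mutation	cic_hgvs_c	cic_hgvs_p	cic_in_blood	cic_polyphen	cic_taster_verdict	cic_taster_prob	cic_assessor_class	cic_exon	fubp1_hgvs_c	fubp1_hgvs_p	fubp1_in_blood
BT1	O III	O	oligo	c.395G>A	del exon 2-20	NA	FALSE	NA	NA	NA	NA	NA	wt	NA	NA
BT2	OA II	OA	oligo	c.395G>A	c.4436A>C	p.(Gln1479Pro)	FALSE	0.967	disease causing	0.99	medium	19	wt	NA	NA
BT3	O III	O	oligo	c.395G>A	wt	NA	NA	NA	NA	NA	NA	NA	wt	NA	NA
BT4	O III	O	oligo	c.395G>A	c.1135-1G>A	NA	FALSE	NA	NA	NA	NA	NA	c.1041G>A	p.(Gln347=)	FALSE
BT5	O II	O	oligo	c.395G>A	c.604C>T	p.(Arg202Trp)	FALSE	1.000	disease causing	0.99	medium	5	c.1041+14T>G	NA	FALSE
BT6	OA III	OA	oligo	c.395G>A	wt	NA	NA	NA	NA	NA	NA	NA	wt	NA	NA
BT7	O III	O	oligo	c.395G>A	c.3347dupC	p.(Ser1117Lysfs*34)	FALSE	NA	NA	NA	NA	NA	c.1623C>G	p.(Tyr541*)	FALSE
BT8	OA II	OA	oligo	c.395G>A	wt	NA	NA	NA	NA	NA	NA	NA	wt	NA	NA
BT9	OA II	OA	oligo	c.395G>A	wt	NA	NA	NA	NA	NA	NA	NA	wt	NA	NA
BT14	O III	O	oligo	c.395G>A	c.601C>T	p.(Arg201Trp)	FALSE	1.000	disease causing	0.99	medium	5	wt	NA	NA
BT15	O II	O	oligo	c.395G>A	c.3131C>A	p.(Ser1044*)	FALSE	NA	NA	NA	NA	NA	wt	NA	NA
BT16	O II	O	oligo	c.395G>A	c.4452C>A	p.(Phe1484Leu)	FALSE	0.965	disease causing	0.99	medium	19	wt	NA	NA
BT11	OA II	OA	astro	c.395G>A	c.3793A>G	p.(Met1265Val)	TRUE	0.000	polymorphism	0.999	neutral	15	wt	NA	NA
BT12	OA III	OA	astro	wt	wt	NA	NA	NA	NA	NA	NA	NA	wt	NA	NA
BT17	OA II	OA	astro	c.395G>A	c.1466G>C	p.(Gly489Ala)	TRUE	0.037	disease causing	0.958	neutral	10	wt	NA	NA
BT13	OA II	OA	other	wt	wt	NA	NA	NA	NA	NA	NA	NA	wt	NA	NA
BT10	O III	O	other	wt	wt	NA	NA	NA	NA	NA	NA	NA	wt	NA	NA
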