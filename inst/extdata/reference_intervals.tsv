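label	kind	value_text	arm	position	printed_value	unit	decimals
RpL19_genomic_rescue	interval	2R:24967017..24970096 Dmel_r6.08	NA	NA	3.08	kbp	2
Xrp1_genomic_rescue	interval	3R:18911505..18927381 Dmel_r6.08	NA	NA	15.88	kbp	2
RpL19_IE-C5_deletion	interval	2R:24968426..24969517 Dmel_r6.08	NA	NA	1.09	kbp	2
Xrp1_mapping_interval	interval	3R:18872668..18979166 Dmel_r6.08	NA	NA	106.5	kbp	1
Xrp1_frameshift_insertion	change	C > GATCCC	3R	18925226	5	bp	0
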