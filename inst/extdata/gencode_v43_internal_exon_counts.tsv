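coding_type	total	ase	sse	other_alt	constitutive
TYPE1_5UTR	5651	3095	308	1537	711
TYPE2_5UC	6610	1247	732	2129	2502
TYPE3_CDS	127144	16129	4036	27852	79127
TYPE4_C3U	1556	571	138	536	311
TYPE5_3UTR	172	58	7	72	35
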