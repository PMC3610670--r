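term_id	description	pop_count	pop_total	study_count	study_total	printed_ratio
bta04510	Focal adhesion	192	27430	93	9829	1.35
bta03040	Spliceosome	126	27430	67	9829	1.48
bta04270	Vascular smooth muscle contraction	122	27430	66	9829	1.51
bta05322	Systemic lupus erythematosus	189	27430	92	9829	1.36
bta04080	Neuroactive ligand-receptor interaction	318	27430	155	9829	1.36
bta04010	MAPK signaling pathway	266	27430	131	9829	1.37
bta01100	Metabolic pathways	1081	27430	471	9829	1.22
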