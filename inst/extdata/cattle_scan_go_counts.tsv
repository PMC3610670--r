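term_id	description	pop_count	pop_total	study_count	study_total	printed_ratio
GO:0000003	reproduction	210	27430	101	9829	1.34
GO:0044421	extracellular region part	361	27430	171	9829	1.32
GO:0016265	death	403	27430	182	9829	1.26
GO:0022414	reproductive process	208	27430	101	9829	1.36
GO:0032991	macromolecular complex	1327	27430	596	9829	1.25
GO:0005623	cell	5024	27430	2264	9829	1.26
GO:0048519	negative regulation of biological process	669	27430	306	9829	1.28
GO:0050896	response to stimulus	1500	27430	693	9829	1.30
GO:0044422	organelle part	1953	27430	885	9829	1.26
GO:0051234	establishment of localization	1094	27430	494	9829	1.26
GO:0031974	membrane-enclosed lumen	728	27430	340	9829	1.30
GO:0022610	biological adhesion	198	27430	94	9829	1.32
GO:0008152	metabolic process	2813	27430	1291	9829	1.28
GO:0044464	cell part	5024	27430	2264	9829	1.26
GO:0003824	catalytic activity	1991	27430	919	9829	1.29
GO:0005488	binding	3393	27430	1534	9829	1.26
GO:0009987	cellular process	3860	27430	1739	9829	1.26
GO:0005215	transporter activity	400	27430	180	9829	1.26
GO:0032502	developmental process	896	27430	409	9829	1.27
GO:0002376	immune system process	390	27430	175	9829	1.25
GO:0008283	cell proliferation	292	27430	142	9829	1.36
GO:0005576	extracellular region	697	27430	320	9829	1.28
GO:0023052	signaling	904	27430	424	9829	1.31
GO:0048518	positive regulation of biological process	785	27430	359	9829	1.28
GO:0032501	multicellular organismal process	1124	27430	494	9829	1.23
GO:0051704	multi-organism process	189	27430	92	9829	1.36
GO:0043226	organelle	3372	27430	1509	9829	1.25
GO:0060089	molecular transducer activity	309	27430	151	9829	1.36
GO:0050789	regulation of biological process	1900	27430	871	9829	1.28
GO:0004872	receptor activity	347	27430	156	9829	1.25
GO:0030234	enzyme regulator activity	261	27430	122	9829	1.30
GO:0040011	locomotion	245	27430	115	9829	1.31
GO:0051179	localization	1269	27430	575	9829	1.26
GO:0040007	growth	165	27430	81	9829	1.37
GO:0071840	cellular component organization or biogenesis	1015	27430	474	9829	1.30
GO:0065007	biological regulation	2029	27430	927	9829	1.28
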