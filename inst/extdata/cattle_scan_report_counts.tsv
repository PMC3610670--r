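quantity	count	total
genes_in_extended_significant_regions	9829	NA
genes_overlapping_milk_qtl_regions	6573	9829
pathways_tested	213	NA
pathways_significant	9	213
gwas_reference_genes	75	NA
gwas_reference_genes_recovered	45	75
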