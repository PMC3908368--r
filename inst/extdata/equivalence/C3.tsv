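# C3 = C3.1 (annotate reads) + C3.2 (per-condition totals) + C3.3 (gene x condition counts)
connector	consumed	reference	produced	rule_id	unused
C3.1	cdna_read_alignment,gene_feature	gene	gene_identifier	read_gene_overlap_annotation	FALSE
C3.2	gene_identifier	absolute_cdna_reads_counting_based_value	condition_read_total	annotated_read_total	FALSE
C3.2	experimental_condition_identifier	experimental_condition	experimental_condition_identifier		FALSE
C3.3	gene_identifier,experimental_condition_identifier	absolute_cdna_reads_counting_based_value	gene_condition_count	per_gene_read_count	FALSE
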