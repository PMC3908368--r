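# C5 = C5.1 (within-category self-self ratios) + C5.2 (cross-category ratios)
connector	consumed	reference	produced	rule_id	unused
C5.1	absolute_intensity_value	ratio_intensity_based_value	self_self_log_ratio	within_category_pairwise_log_ratio	FALSE
C5.1	gene_identifier	gene	gene_identifier		FALSE
C5.2	absolute_intensity_value	ratio_intensity_based_value	cross_category_log_ratio	cross_category_pairwise_log_ratio	FALSE
C5.2	gene_identifier	gene	gene_identifier		FALSE
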