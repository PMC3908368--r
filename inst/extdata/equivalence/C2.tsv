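# C2: differential-expression matrix -> KEGG Mapper color list
connector	consumed	reference	produced	rule_id	unused
C2	experiment_specific_gene_identifier	gene	kegg_identifier	experiment_to_kegg_mapping	FALSE
C2	experimental_condition_identifier,log_ratio_value,gene_expression_threshold	ratio_intensity_based_value	regulation_color	threshold_regulation_classification	FALSE
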