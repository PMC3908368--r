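# C1: merge per-condition two-color ratio files into one multi-column dataset
connector	consumed	reference	produced	rule_id	unused
C1	gene_identifier	gene	gene_identifier		FALSE
C1	experimental_condition_identifier	experimental_condition	experimental_condition_identifier		FALSE
C1	log_ratio_value	ratio_intensity_based_value	log_ratio_value		FALSE
C1	soft_metadata_line				TRUE
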