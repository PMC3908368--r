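# C6: filter HTself results into a gene list for functional analysis
connector	consumed	reference	produced	rule_id	unused
C6	gene_identifier,htself_value,p_value	gene	selected_gene_identifier	significance_threshold_filter	FALSE
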