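# C4: library-size normalization of read counts
connector	consumed	reference	produced	rule_id	unused
C4	gene_condition_count,condition_read_total	relative_cdna_reads_counting_based_value	normalized_count	library_size_division	FALSE
C4	gene_identifier	gene	gene_identifier		FALSE
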