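# GEXPO reference ontology: typed relation edges
# subject<TAB>relation<TAB>object
#
# --- gene expression process ---
gene_expression	is_a	biological_process
transcription	part_of	gene_expression
rna_processing	part_of	gene_expression
translation	part_of	gene_expression
protein_maturation	part_of	gene_expression
rna_processing	preceded_by	transcription
translation	preceded_by	rna_processing
protein_maturation	preceded_by	translation
primary_transcript	produced_by	transcription
transcription	has_participant	gene
rna_processing	has_participant	primary_transcript
mature_transcript	produced_by	rna_processing
ncrna	is_a	mature_transcript
mrna	is_a	mature_transcript
protein	produced_by	translation
translation	has_participant	mrna
protein_maturation	has_participant	protein
#
# --- gene expression measurement process ---
biological_experimental_process	affected_by	experimental_condition
gene_expression_measurement	is_a	biological_experimental_process
hybridization_based_gene_expression_measurement	is_a	gene_expression_measurement
sequencing_based_gene_expression_measurement	is_a	gene_expression_measurement
dna_microarray_experimental_process	is_a	hybridization_based_gene_expression_measurement
one_color_microarray_experimental_process	is_a	dna_microarray_experimental_process
two_color_microarray_experimental_process	is_a	dna_microarray_experimental_process
rna_seq_experimental_process	is_a	sequencing_based_gene_expression_measurement
#
# --- expression-value hierarchy ---
fluorescence_intensity_based_value	is_a	gene_expression_value
sequence_counting_based_value	is_a	gene_expression_value
absolute_intensity_based_value	is_a	fluorescence_intensity_based_value
ratio_intensity_based_value	is_a	fluorescence_intensity_based_value
absolute_intensity_based_value	produced_by	one_color_microarray_experimental_process
ratio_intensity_based_value	produced_by	two_color_microarray_experimental_process
cdna_reads_counting_based_value	is_a	sequence_counting_based_value
cdna_reads_counting_based_value	produced_by	rna_seq_experimental_process
absolute_cdna_reads_counting_based_value	is_a	cdna_reads_counting_based_value
relative_cdna_reads_counting_based_value	is_a	cdna_reads_counting_based_value
gene_expression_value	quantifies	gene
#
# --- DNA microarray experimental process ---
microarray_manufacturing	part_of	dna_microarray_experimental_process
microarray_washing	part_of	dna_microarray_experimental_process
microarray_image_acquisition	part_of	dna_microarray_experimental_process
microarray_gene_expression_profiling	part_of	dna_microarray_experimental_process
dna_microarray_experimental_process	has_part	rna_extraction
dna_microarray_experimental_process	has_part	reverse_transcription
dna_microarray_experimental_process	has_part	cdna_labeling
dna_microarray_experimental_process	has_part	hybridization
microarray_manufacturing	has_participant	probe
rna_extraction	has_participant	mature_transcript
cdna	produced_by	reverse_transcription
reverse_transcription	has_participant	mature_transcript
cdna_labeling	has_participant	cdna
microarray_image	produced_by	microarray_image_acquisition
microarray_gene_expression_profiling	has_participant	microarray_image
cdna_labeling	preceded_by	reverse_transcription
microarray_washing	preceded_by	hybridization
microarray_image_acquisition	preceded_by	microarray_washing
microarray_gene_expression_profiling	preceded_by	microarray_image_acquisition
#
# --- RNA-Seq experimental process ---
rna_seq_gene_expression_profiling	part_of	rna_seq_experimental_process
rna_seq_experimental_process	has_part	rna_extraction
rna_seq_experimental_process	has_part	reverse_transcription
rna_seq_experimental_process	has_part	cdna_library_with_adaptors_preparation
rna_seq_experimental_process	has_part	cdna_next_generation_sequencing
rna_seq_experimental_process	has_part	alignment_of_cdna_read_to_a_reference_genome
rna_seq_experimental_process	has_part	de_novo_assembly_of_cdna_reads
cdna_library_with_adaptors_preparation	has_participant	cdna
cdna_next_generation_sequencing	has_participant	cdna
cdna_read	produced_by	cdna_next_generation_sequencing
cdna_read	derives_from	cdna
alignment_of_cdna_read_to_a_reference_genome	has_participant	cdna_read
alignment_of_cdna_read_to_a_reference_genome	has_participant	reference_genome
de_novo_assembly_of_cdna_reads	has_participant	cdna_read
rna_seq_gene_expression_profiling	has_participant	cdna_read
cdna_library_with_adaptors_preparation	preceded_by	reverse_transcription
# choice: profiling is preceded by exactly one of the two alternative steps;
# the alternative (choice) structure has no edge notation here, so both
# branches are recorded as ordinary preceded_by edges.
rna_seq_gene_expression_profiling	preceded_by	alignment_of_cdna_read_to_a_reference_genome
rna_seq_gene_expression_profiling	preceded_by	de_novo_assembly_of_cdna_reads
#
# --- root attachments: concepts with no declared is_a parent sit under thing ---
biological_process	is_a	thing
transcription	is_a	thing
rna_processing	is_a	thing
translation	is_a	thing
protein_maturation	is_a	thing
gene	is_a	thing
primary_transcript	is_a	thing
mature_transcript	is_a	thing
protein	is_a	thing
biological_experimental_process	is_a	thing
experimental_condition	is_a	thing
gene_expression_value	is_a	thing
microarray_manufacturing	is_a	thing
microarray_washing	is_a	thing
microarray_image_acquisition	is_a	thing
microarray_gene_expression_profiling	is_a	thing
rna_extraction	is_a	thing
reverse_transcription	is_a	thing
cdna_labeling	is_a	thing
hybridization	is_a	thing
probe	is_a	thing
cdna	is_a	thing
microarray_image	is_a	thing
rna_seq_gene_expression_profiling	is_a	thing
cdna_library_with_adaptors_preparation	is_a	thing
cdna_next_generation_sequencing	is_a	thing
alignment_of_cdna_read_to_a_reference_genome	is_a	thing
de_novo_assembly_of_cdna_reads	is_a	thing
cdna_read	is_a	thing
reference_genome	is_a	thing
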