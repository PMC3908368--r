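# GEXPO reference ontology: concept registry
# id<TAB>label<TAB>source   (source: introduced | gene_ontology | sequence_ontology)
thing	Thing	introduced
# gene expression process
biological_process	biological process	gene_ontology
gene_expression	gene expression	gene_ontology
transcription	transcription	gene_ontology
rna_processing	RNA processing	gene_ontology
translation	translation	gene_ontology
protein_maturation	protein maturation	gene_ontology
gene	gene	sequence_ontology
primary_transcript	primary transcript	sequence_ontology
mature_transcript	mature transcript	sequence_ontology
ncrna	ncRNA	sequence_ontology
mrna	mRNA	sequence_ontology
protein	protein	sequence_ontology
# gene expression measurement process and the expression-value hierarchy
biological_experimental_process	biological experimental process	introduced
experimental_condition	experimental condition	introduced
gene_expression_measurement	gene expression measurement	introduced
hybridization_based_gene_expression_measurement	hybridization-based gene expression measurement	introduced
sequencing_based_gene_expression_measurement	sequencing-based gene expression measurement	introduced
dna_microarray_experimental_process	DNA microarray experimental process	introduced
one_color_microarray_experimental_process	one-color microarray experimental process	introduced
two_color_microarray_experimental_process	two-color microarray experimental process	introduced
rna_seq_experimental_process	RNA-Seq experimental process	introduced
gene_expression_value	gene expression value	introduced
fluorescence_intensity_based_value	fluorescence intensity-based value	introduced
sequence_counting_based_value	sequence counting-based value	introduced
absolute_intensity_based_value	absolute intensity-based value	introduced
ratio_intensity_based_value	ratio intensity-based value	introduced
cdna_reads_counting_based_value	cDNA reads counting-based value	introduced
absolute_cdna_reads_counting_based_value	absolute cDNA reads counting-based value	introduced
relative_cdna_reads_counting_based_value	relative cDNA reads counting-based value	introduced
# DNA microarray experimental process
microarray_manufacturing	microarray manufacturing	introduced
microarray_washing	microarray washing	introduced
microarray_image_acquisition	microarray image acquisition	introduced
microarray_gene_expression_profiling	microarray gene expression profiling	introduced
rna_extraction	RNA extraction	introduced
reverse_transcription	reverse transcription	gene_ontology
cdna_labeling	cDNA labeling	introduced
hybridization	hybridization	introduced
probe	probe	sequence_ontology
cdna	cDNA	sequence_ontology
microarray_image	microarray image	introduced
# RNA-Seq experimental process
rna_seq_gene_expression_profiling	RNA-Seq gene expression profiling	introduced
cdna_library_with_adaptors_preparation	cDNA library with adaptors preparation	introduced
cdna_next_generation_sequencing	cDNA next-generation sequencing	introduced
alignment_of_cdna_read_to_a_reference_genome	alignment of cDNA read to a reference genome	introduced
de_novo_assembly_of_cdna_reads	de novo assembly of cDNA reads	introduced
cdna_read	cDNA read	introduced
reference_genome	reference genome	introduced
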