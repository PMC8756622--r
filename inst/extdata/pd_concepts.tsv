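concept_id	name	is_query
OMOP:4182210	Parkinson's disease	TRUE
OMOP:4152048	Parkinsonism	TRUE
OMOP:4101469	Arteriosclerotic Parkinsonism	TRUE
OMOP:4047747	Dementia associated with Parkinson's Disease	TRUE
OMOP:4323241	Neuroleptic-induced Parkinsonism	TRUE
OMOP:0378419	Alzheimer's disease	FALSE
OMOP:0380378	Epilepsy	FALSE
OMOP:0318736	Migraine	FALSE
OMOP:0495241	Schizophrenia	FALSE
OMOP:0333951	Huntington's chorea	FALSE
OMOP:0432309	Restless legs syndrome	FALSE
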