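vocabulary	code	outcome_label
icd10	I50.0	hf
icd10	I50.1	hf
icd10	I50.9	hf
icd10	I20.9	chd
icd10	I21.9	chd
icd10	I25.1	chd
icd10	I25.9	chd
icd10	N18.3	ckd
icd10	N18.4	ckd
icd10	N18.5	ckd
icd10	N18.9	ckd
icd10	I61.9	stroke
icd10	I63.9	stroke
icd10	I64	stroke
icd10	R60.0	oedema
icd10	R60.9	oedema
icd9	4280	hf
icd9	4139	chd
icd9	5859	ckd
icd9	4369	stroke
icd9	7823	oedema
read2	G58..	hf
read2	G33..	chd
read2	K05..	ckd
read2	G66..	stroke
read2	R023.	oedema
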