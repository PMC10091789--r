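code_system	code	drug_name	drug_class
bnf	0206020A0	amlodipine	dccb_amlodipine
bnf	0206020R0	nifedipine	dccb_other
bnf	0206020F0	felodipine	dccb_other
bnf	0206020L0	lacidipine	dccb_other
bnf	0206020T0	lercanidipine	dccb_other
bnf	0205051R0	ramipril	ace
bnf	0205051L0	lisinopril	ace
bnf	0205052N0	losartan	arb
bnf	0205052C0	candesartan	arb
bnf	0204000E0	atenolol	beta_blocker
bnf	0204000H0	bisoprolol	beta_blocker
bnf	0202010B0	bendroflumethiazide	diuretic
bnf	0202010F0	indapamide	diuretic
bnf	0202080D0	doxazosin	alpha_blocker
bnf	0205010J0	hydralazine	vasodilator
bnf	0407010H0	paracetamol	other
read2	bxd1.	amlodipine	dccb_amlodipine
read2	bxd2.	nifedipine	dccb_other
read2	bxi1.	ramipril	ace
read2	bxb1.	atenolol	beta_blocker
read2	bxt1.	bendroflumethiazide	diuretic
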