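gene	variant_id	participant_id	heteroplasmy_pct	n_domains	domain_labels	clinvar_lp	structure_exception
ATP6	m.8939T>C	53		6	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine,immunological	0	0
COX2	m.7673A>G	20		6	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine,immunological	0	0
COX2	m.7761A>G	33		6	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine,immunological	0	0
COX3	m.9738G>A	14		1	neuromuscular	0	0
CYB	m.15740C>T	74	94	6	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine,immunological	0	0
CYB	m.15884G>A	12		3	neuromuscular,neurodevelopmental,neuropsychiatric	0	0
ND1	m.3565A>C	42		1	neuromuscular	0	0
ND5	m.12706T>C	39		6	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine,immunological	1	0
TA	m.15904C>T	19	39	5	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine	0	1
TG	m.10003T>C	51		2	neuromuscular,neurodevelopmental	0	0
TM	m.4464A>G	25		2	neuromuscular,neurodevelopmental	0	0
TR	m.10410T>A	39		4	neuromuscular,neurodevelopmental,neuropsychiatric,functional	0	1
TT	m.15907A>G	41		4	neuromuscular,neurodevelopmental,neuropsychiatric,functional	0	1
multiple	del_m.492-14240	73	46	5	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine	0	0
multiple	del_m.6468-14148	unnumbered		6	neuromuscular,neurodevelopmental,neuropsychiatric,functional,endocrine,immunological	0	0
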