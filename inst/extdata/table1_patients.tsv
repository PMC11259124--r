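patient_id	hgvs_c	hgvs_p	age	sex	primary_phenotype	additional_phenotype
Patient 1	c.208C>T	p.Gln70Ter	58	male	LVH
Patient 2	c.691C>T	p.Gln231Ter	78	male	LVH
Patient 3	c.691C>T	p.Gln231Ter	53	male	LVH
Patient 4	c.691C>T	p.Gln231Ter	66	male	LVH
Patient 5	c.691C>T	p.Gln231Ter	26	male	LVH
Patient 6	c.691C>T	p.Gln231Ter	70	male	LVH	Syncope, pain
Patient 7	c.2841_2848del	p.Gly948GlufsTer3	64	male	LVH
Patient 8	c.3175C>T	p.Arg1059Ter	65	male	LVH
Patient 9	c.3340C>T	p.Arg1114Ter	24	male	LVH	Left ventricular diastolic dysfunction
Patient 10	c.3409_3436del	p.Pro1137ArgfsTer3	32	male	LVH	Arrhythmias
Patient 11	c.3409_3436del	p.Pro1137ArgfsTer3	34	male	LVH	Proteinuria
Patient 13	c.3409_3436del	p.Pro1137ArgfsTer3	31	male	LVH
Patient 14	c.3409_3436del	p.Pro1137ArgfsTer3	63	female	LVH	Arrhythmias
Patient 15	c.3580dup	p.Arg1194ProfsTer62	47	male	LVH
Patient 16	c.3580dup	p.Arg1194ProfsTer62	51	male	LVH	Hypertension
Patient 17	c.3580dup	p.Arg1194ProfsTer62	40	male	LVH	Heart failure
Patient 18	c.3635_3636del	p.Arg1212ThrfsTer43	51	male	LVH	Hypertension
Patient 19	c.3635_3636del	p.Arg1212ThrfsTer43	70	male	LVH
Patient 20	c.3691G>T	p.Glu1231Ter	43	female	LVH	Arrhythmia, nerve conduction abnormalities
Patient 21	c.3965+2T>G	p.?	61	male	LVH
Patient 22	c.4198dup	p.Asp1400GlyfsTer58	63	male	LVH
Patient 23	c.4199del	p.Asp1400AlafsTer8	77	male	LVH	Proteinuria
Patient 24	c.4234C>T	p.Arg1412Ter	50	male	LVH	Heart failure
Patient 25	c.4234C>T	p.Arg1412Ter	51	male	LVH	Pain
Patient 27	c.4234C>T	p.Arg1412Ter	82	male	LVH
Patient 28	c.4234C>T	p.Arg1412Ter	41	male	LVH
Patient 29	c.4234C>T	p.Arg1412Ter	59	male	LVH
Patient 30	c.4724-1G>A	p.?	55	male	LVH	Syncope
Patient 31	c.4724-1G>A	p.?	58	female	LVH
Patient 32	c.4724-1G>A	p.?	48	male	LVH
Patient 33	c.4724-1G>A	p.?	67	male	LVH	Heart failure
Patient 34	c.4724-1G>A	p.?	51	male	LVH	Syncope
Patient 35	c.4724-1G>A	p.?	39	male	LVH
Patient 36	c.4724-1G>A	p.?	87	female	LVH
Patient 37	c.4768C>T	p.Arg1590Ter	28	male	LVH
Patient 38	c.4768C>T	p.Arg1590Ter	17	male	LVH	Syncope
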