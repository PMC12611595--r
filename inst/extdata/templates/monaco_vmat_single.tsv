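# dialect: monaco_vmat_single
# n: 45
# min_level: 25
# organs: organ
structure	cost	weight	reference_dose_cGy	isoconstraint
Ring 45	target_penalty	10	-	4500
Ring 44	overdose_dvh	0.01	4500	0.01
Ring 43	overdose_dvh	0.01	4400	0.01
Ring 42	overdose_dvh	0.01	4300	0.01
Ring 41	overdose_dvh	0.01	4200	0.01
Ring 40	overdose_dvh	0.01	4100	0.01
Ring 39	overdose_dvh	0.01	4000	0.01
Ring 38	overdose_dvh	0.01	3900	0.01
Ring 37	overdose_dvh	0.01	3800	0.01
Ring 36	overdose_dvh	0.01	3700	0.01
Ring 35	overdose_dvh	0.01	3600	0.01
Ring 34	overdose_dvh	0.01	3500	0.01
Ring 33	overdose_dvh	0.01	3400	0.01
Ring 32	overdose_dvh	0.01	3300	0.01
Ring 31	overdose_dvh	0.01	3200	0.01
Ring 30	overdose_dvh	0.01	3100	0.01
Ring 29	overdose_dvh	0.01	3000	0.01
Ring 28	overdose_dvh	0.01	2900	0.01
Ring 27	overdose_dvh	0.01	2800	0.01
Ring 26	overdose_dvh	0.01	2700	0.01
Ring 25	overdose_dvh	0.01	2600	0.01
Body	maximum_dose	1	-	5000
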