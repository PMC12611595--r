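# dialect: pinnacle_imrt
# n: 45
# min_level: 25
# organs: organ
structure	cost	weight	reference_dose_cGy	isoconstraint
Ring 45	minimum_dose	100	4500	-
Ring 45	maximum_dose	80	4650	-
Ring 45	min_dvh	100	4500	100
Ring 45	uniform_dose	10	4550	-
Ring 44	maximum_dose	0.01	4500	-
Ring 43	maximum_dose	0.01	4400	-
Ring 42	maximum_dose	0.01	4300	-
Ring 41	maximum_dose	0.01	4200	-
Ring 40	maximum_dose	0.01	4100	-
Ring 39	maximum_dose	0.01	4000	-
Ring 38	maximum_dose	0.01	3900	-
Ring 37	maximum_dose	0.01	3800	-
Ring 36	maximum_dose	0.01	3700	-
Ring 35	maximum_dose	0.01	3600	-
Ring 34	maximum_dose	0.01	3500	-
Ring 33	maximum_dose	0.01	3400	-
Ring 32	maximum_dose	0.01	3300	-
Ring 31	maximum_dose	0.01	3200	-
Ring 30	maximum_dose	0.01	3100	-
Ring 29	maximum_dose	0.01	3000	-
Ring 28	maximum_dose	0.01	2900	-
Ring 27	maximum_dose	0.01	2800	-
Ring 26	maximum_dose	0.01	2700	-
Ring 25	maximum_dose	0.01	2600	-
Ring 30 ∩ organ	maximum_dose	0.01	3000	-
Ring 33 ∩ organ	maximum_dose	0.01	3300	-
Ring 36 ∩ organ	maximum_dose	0.01	3600	-
Ring 39 ∩ organ	maximum_dose	0.01	3900	-
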