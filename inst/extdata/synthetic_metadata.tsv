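sample_id	experiment	treatment	dilution_factor	replicate	timepoint
synthExp1_T0	synthExp1	source	NA	NA	T0
synthExp1_P_d25_r1	synthExp1	protists	0.25	1	T12
synthExp1_P_d25_r2	synthExp1	protists	0.25	2	T12
synthExp1_P_d50_r1	synthExp1	protists	0.5	1	T12
synthExp1_P_d50_r2	synthExp1	protists	0.5	2	T12
synthExp1_P_d75_r1	synthExp1	protists	0.75	1	T12
synthExp1_P_d75_r2	synthExp1	protists	0.75	2	T12
synthExp1_P_d100_r1	synthExp1	protists	1	1	T12
synthExp1_P_d100_r2	synthExp1	protists	1	2	T12
synthExp1_PV_d25_r1	synthExp1	protists_viruses	0.25	1	T12
synthExp1_PV_d25_r2	synthExp1	protists_viruses	0.25	2	T12
synthExp1_PV_d50_r1	synthExp1	protists_viruses	0.5	1	T12
synthExp1_PV_d50_r2	synthExp1	protists_viruses	0.5	2	T12
synthExp1_PV_d75_r1	synthExp1	protists_viruses	0.75	1	T12
synthExp1_PV_d75_r2	synthExp1	protists_viruses	0.75	2	T12
synthExp1_PV_d100_r1	synthExp1	protists_viruses	1	1	T12
synthExp1_PV_d100_r2	synthExp1	protists_viruses	1	2	T12
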