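gene	cpg	indirect	indirect_se	indirect_p	direct	direct_se	direct_p	total	total_se	total_fdr
NDUFS5	cg07388493	-0.097	0.014	2.7e-12	-0.09	0.03	1.9e-03	-0.19	0.03	1.2e-08
MRPL34	cg17328880	-0.070	0.010	7.6e-12	-0.07	0.03	4.8e-03	-0.14	0.03	3.0e-06
IL10RA	cg18728264	-0.020	0.006	4.3e-04	0.21	0.03	1.7e-13	0.19	0.03	1.5e-08
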