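snp	model	p_disc	p_rep1	p_rep2	meta_reported
rs7161	unt_add	0.044	0.699	0.146	0.054
rs7161	log_add	0.080	0.791	0.153	0.103
rs7161	unt_dom	0.030	0.329	0.208	0.024
rs7161	log_dom	0.050	0.400	0.258	0.051
rs4660761	unt_add	0.020	0.908	0.233	0.091
rs4660761	log_add	0.026	0.929	0.343	0.156
rs4660761	unt_dom	0.012	0.493	0.726	0.108
rs4660761	log_dom	0.013	0.651	0.909	0.269
rs1800934	unt_add	0.090	0.682	0.251	0.126
rs1800934	log_add	0.027	0.854	0.142	0.059
rs1800934	unt_dom	0.091	0.688	0.184	0.102
rs1800934	log_dom	0.020	0.927	0.135	0.065
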