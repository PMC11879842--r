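canonical_name	model_id
formate	for_c
thf	thf_c
f10thf	f10thf_c
methenylthf	methenylthf_c
atp	atp_c
adp	adp_c
pi	pi_c
h	h_c
h2o	h2o_c
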