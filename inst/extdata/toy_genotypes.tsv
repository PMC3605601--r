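snp_id	d1	d2	d3	d4
rs1	AA	AB	BB	NN
rs2	AB	AB	AA	BB
rs3	BB	AA	AB	AA
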