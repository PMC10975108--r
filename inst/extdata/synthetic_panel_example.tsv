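snp_id	effect_allele	other_allele	beta	source_maf
rs6727262	C	T	0.00877977218036209	0.0548394446610473
rs4853253	C	T	-0.00834164095108911	0.322939734440297
rs9058738	C	A	0.00808422627301624	0.146632492879871
rs3081319	A	T	-0.0043601319373753	0.291534421104006
rs2584402	A	G	0.00426598516202099	0.406209617177956
rs8547298	G	C	0.0239126246532914	0.373435368691571
rs3222197	G	T	-0.00314641452046862	0.145024598995224
rs4405038	T	A	-0.0248692987313623	0.0548330669756979
rs8611015	T	C	0.0200942498687326	0.441015577910002
rs7024853	G	C	-0.00687005154416058	0.455759726231918
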