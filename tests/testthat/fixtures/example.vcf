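##fileformat=VCFv4.2
##contig=<ID=1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype posterior probabilities">
##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
1	100	rs1	A	G	.	PASS	.	GT:GP:PL:DS	0/0:1,0,0:0,30,60:0	0/1:0.1,0.6,0.3:10,0,10:0.9
1	200	rs2	C	T	.	PASS	.	GT:GP:PL:DS	1/1:0,0,1:60,30,0:2	./.:.:.:.
1	300	rs3	G	A,T	.	PASS	.	GT:GP:PL:DS	0/1:0.2,0.5,0.3,0,0,0:5,0,9,99,99,99:1.1	0/0:1,0,0,0,0,0:0,20,40,99,99,99:0
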