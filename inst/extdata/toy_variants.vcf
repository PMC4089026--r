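##fileformat=VCFv4.2
##INFO=<ID=ANN,Number=1,Type=String,Description="Functional annotation">
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">
##contig=<ID=chr1,length=1000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	101	.	A	G	.	PASS	ANN=exonic;GENE=geneA
chr1	250	.	C	T	.	PASS	ANN=intronic;GENE=geneA
chr1	400	.	CTT	C	.	PASS	ANN=exonic;GENE=geneB
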