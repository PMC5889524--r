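##fileformat=VCFv4.2
##source=popdrift
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	EAST_001	EAST_002	EAST_003	EAST_004	EAST_005	EAST_006	WEST_001	WEST_002	WEST_003	WEST_004	WEST_005	WEST_006
1	800000	snp000001	A	G	.	PASS	.	GT	1/1	0/1	1/1	1/1	0/0	0/1	0/1	0/1	0/1	0/1	0/0	1/1
1	1600000	snp000002	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/0
1	2400000	snp000003	A	G	.	PASS	.	GT	1/1	0/1	1/1	1/1	1/1	1/1	0/1	0/1	0/1	0/1	1/1	1/1
1	3200000	snp000004	A	G	.	PASS	.	GT	1/1	0/1	1/1	0/0	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1
1	4000000	snp000005	A	G	.	PASS	.	GT	1/1	1/1	1/1	0/1	0/1	0/0	0/0	0/0	0/0	1/1	0/1	0/1
1	4800000	snp000006	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	0/1	0/1	0/1	1/1	1/1	0/1	1/1
1	5600000	snp000007	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	0/1	0/0	0/1	1/1	0/1	0/1	1/1	0/1
1	6400000	snp000008	A	G	.	PASS	.	GT	0/1	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/0	0/1
1	7200000	snp000009	A	G	.	PASS	.	GT	0/1	1/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	1/1
1	8000000	snp000010	A	G	.	PASS	.	GT	0/1	0/0	0/0	1/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0
1	8800000	snp000011	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	0/1	0/1	1/1	1/1	0/1	0/1	1/1	1/1
1	9600000	snp000012	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0
1	10400000	snp000013	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1
1	11200000	snp000014	A	G	.	PASS	.	GT	0/1	0/1	1/1	1/1	0/1	1/1	1/1	0/1	0/0	1/1	0/1	0/1
1	12000000	snp000015	A	G	.	PASS	.	GT	0/1	1/1	0/1	1/1	0/1	1/1	1/1	0/1	1/1	0/1	1/1	0/1
1	12800000	snp000016	A	G	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/1	1/1	0/0	1/1	1/1
1	13600000	snp000017	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/1	0/1	0/1	0/0	0/1	1/1	0/1	0/0	0/0
1	14400000	snp000018	A	G	.	PASS	.	GT	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/0	1/1	0/0	0/0	0/1
1	15200000	snp000019	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0
1	16000000	snp000020	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1
1	16800000	snp000021	A	G	.	PASS	.	GT	1/1	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/1
1	17600000	snp000022	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/0
1	18400000	snp000023	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/1	0/1	1/1	0/0	1/1
1	19200000	snp000024	A	G	.	PASS	.	GT	0/0	0/1	1/1	0/1	1/1	1/1	1/1	0/1	0/1	0/1	1/1	1/1
1	20000000	snp000025	A	G	.	PASS	.	GT	1/1	1/1	1/1	0/1	0/1	0/1	1/1	1/1	1/1	1/1	1/1	1/1
1	20800000	snp000026	A	G	.	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/1	1/1	0/1	1/1	1/1	0/1	0/1
1	21600000	snp000027	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	22400000	snp000028	A	G	.	PASS	.	GT	0/1	1/1	0/1	0/1	1/1	1/1	0/1	0/1	0/1	1/1	0/1	1/1
1	23200000	snp000029	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	24000000	snp000030	A	G	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1
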