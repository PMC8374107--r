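id	sequence	length	detected_in	proposed_name
id21	AGCTTCTTTACAGTGTTGCCT	21	S-EVs	hsa-miR-107-5p
id69	CAGAGTCTCGTTCTGTTGCCC	21	S-EVs	hsa-miR-1273c-3p
id335	ACTTCCCCCACCTCACTGCCC	21	S-EVs	hsa-miR-3138-5p
id344	CCTGTAATCCCAGCATTT	18	S-EVs	hsa-miR-3159-3p
id379	CCTCATCTGTCTGTTGGGCT	20	cells	hsa-miR-326-5p
id535	AAACTCAGTAATGGTAACGGTTT	23	cells	hsa-miR-451b-3p
id713	CCCCTCAGTCCACCAGAGCCCGGA	24	S-EVs	hsa-miR-760-5p
id716	CGGGTCTCGGCCCGTACAGTCCGG	24	S-EVs	hsa-miR-762-5p
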