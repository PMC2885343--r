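name	length	centromere_start	centromere_end	acrocentric	is_sex
chr1	8e+07	44147855	46547855	0	0
chr2	8e+07	36998460	39398460	0	0
chr3	8e+07	36146713	38546713	0	0
chr4	8e+07	37143577	39543577	0	0
chr5	8e+07	41215515	43615515	0	0
chr6	8e+07	38002925	40402925	0	0
chr7	8e+07	37100564	39500564	0	0
chr8	8e+07	36430258	38830258	0	0
chrX	8e+07	3.6e+07	38400000	0	1
chrY	3.2e+07	14400000	16800000	0	1
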