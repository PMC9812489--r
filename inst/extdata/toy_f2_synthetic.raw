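FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_G snp3_T
F1 id1 0 0 1 -9 0 1 2
F1 id2 0 0 2 -9 2 0 1
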