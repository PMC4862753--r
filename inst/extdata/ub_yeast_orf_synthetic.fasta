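>ub_yeast_orf_synthetic representative yeast ubiquitin coding sequence (codons chosen per common yeast usage; synthetic construct)
ATGCAAATTTTTGTTAAAACTTTGACTGGTAAAACTATTACTTTGGAAGTTGAATCTTCTGATACTATTGATAATGTTAAATCTAAAATTCAAGATAAAGAAGGTATTCCACCAGATCAACAAAGATTGATTTTTGCTGGTAAACAATTGGAAGATGGTAGAACTTTGTCTGATTATAATATTCAAAAAGAATCTACTTTGCATTTGGTTTTGAGATTGAGAGGTGGT
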