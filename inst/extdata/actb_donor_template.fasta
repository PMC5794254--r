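>actb_donor_template published HDR donor for the beta-coded gamma-actin knock-in (5' Actb region)
CGGCTGTTGGCGGCCCCGAGGTGACTATAGCCTTCTTTTGTGTCTTGATAGTAGTTCGCC
ATGGAAGAGGAAATCGCTGCGCTGGTCATTGACAACGGCTCCGGCATGTGCAAAGCCGGC
TTCGCGGGCGACGATGCTCCCCGGGCTGTA
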