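>actb_wt_5prime_reconstructed RECONSTRUCTED (not downloaded) wild-type mouse Actb 5' CDS fragment, codons 1-30; derived from the published donor template by reverting the five knock-in point mutations, constrained by the published guide protospacer (codons 6-10), the EcoRV site spanning codons 4-5, and the canonical beta-actin N-terminal decapeptide MDDDIAALVV
ATGGATGACGATATCGCTGCGCTGGTCGTCGACAACGGCTCCGGCATGTGCAAAGCCGGC
TTCGCGGGCGACGATGCTCCCCGGGCTGTA
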