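>FLT3_amplicon_synthetic synthetic 360-bp stand-in for the focused FLT3-ITD PCR product (assay primers flanking a screened random insert)
GCAATTTAGGTATGAAAGCCAGCAGCCTTAAATAACGAGCTTCGGGTGACATTGCACTTA
CTCGAGTAACCCGCGTGAGTAAGACTTATCATCACAGCCGTTTTACGCCCTGGAGTCATA
AACACAATGTACATGAGAGCCAGATATCAGTTATCTAACGTCGTGATAGAAACGGTAGGC
AGAGCGCATCCATCTGAAGGATTTCCGTAAATTGATGTCAGAATCCTACTCACTCCTTGA
GAGCCGTCGACTGCGCCATCTTGGCGCACTCTAGCGGTCTCACCGCTGGGCCGCTGTATC
GACAATATCCGCGAGTGAGATTATCTCCTTTCCCCAAGGTTGCCGTCAAAATGCTGAAAG
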