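>pZQ3_core printed core (block 3-6) of the pZQ3 moderate-activity control plasmid
GGCTCCGAATTCGCCCTTTTCCCAGGGCGGCAGAGGCAAAAATTTGCCGATCCCAGAGCC
AGCCGACTCATTCAAAGCTCCGACTTCGTTGCGTGCACACAGAGTCTCAAGGGCGACCCA
GCTTT
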