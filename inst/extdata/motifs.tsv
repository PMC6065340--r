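# Control-region motif definitions. The TAS consensus is the published
# 17-mer for Nanorana; the CSB-1/2/3 and OH entries are SYNTHETIC
# placeholder consensus sequences in the style of vertebrate conserved
# sequence blocks (the published CSB alignments are available only as a
# figure), intended to be edited for a given study system. Consensus may
# use IUPAC ambiguity codes; max_mismatch is the per-motif Hamming budget.
name	consensus	max_mismatch
TAS	TATAAGACATCTATGTA	2
CSB-1	TTAATGCTTGTAGGACATAATAATAACA	3
CSB-2	CAAACCCCCCCTCCCCCGC	2
CSB-3	TGCCAAACCCCAAAAACA	2
OH	CCACGTGAGGTGCATCCATTCACCATTCTCGCTGACAACGTTACTCCGCGTTTGAGGAATGCGTCAACGAAA	6
GACAT	GACAT	0
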