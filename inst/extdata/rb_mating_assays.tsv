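# Reciprocal assortative-mating assay counts for the RbMM/RbSS recombinant
# strains: choosers were given mates with X-islands matching or not matching
# their own island type; two replicates per mating combination.
replicate	chooser	offered	n_assortative	n_disassortative
1	MM	M S	29	1
2	MM	M S	24	0
1	SS	M S	25	0
2	SS	M S	25	0
1	M	MM SS	15	16
2	M	MM SS	17	8
1	S	MM SS	18	13
2	S	MM SS	11	20
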