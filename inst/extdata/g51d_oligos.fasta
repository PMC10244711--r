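>gRNA_SNCA_exon3 20-nt protospacer targeting rat SNCA exon 3
GTCGTTCATGGAGTGACAAC
>donor_ssDNA_G51D 80-nt single-stranded donor; GGA->GAT codon edit in lower case
CAATTCTTTTTTTAGGTTCCAAAACTAAGGAGGGAGTCGTTCATGatGTGACAACAGGTAAGCTCTGTTGTCTTTTATCC
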