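# organism name or alias <TAB> NCBI taxonomy id
# Small bundled vocabulary of common model organisms; override with your own
# file via load_vocabulary(taxa = ...) or the CLI --vocab flag.
Gallus gallus	9031
chicken	9031
Homo sapiens	9606
human	9606
Mus musculus	10090
mouse	10090
Rattus norvegicus	10116
rat	10116
Danio rerio	7955
zebrafish	7955
Drosophila melanogaster	7227
fruit fly	7227
Caenorhabditis elegans	6239
Saccharomyces cerevisiae	4932
Schizosaccharomyces pombe	4896
Escherichia coli	562
Bacillus subtilis	1423
Arabidopsis thaliana	3702
Zea mays	4577
Oryza sativa	4530
Sus scrofa	9823
pig	9823
Bos taurus	9913
cattle	9913
Ovis aries	9940
sheep	9940
Canis lupus familiaris	9615
dog	9615
Macaca mulatta	9544
Xenopus laevis	8355
Oryctolagus cuniculus	9986
rabbit	9986
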