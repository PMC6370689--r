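Package: rnrclassify
Title: Class and Subclass Annotation of Ribonucleotide Reductase Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based (re)annotation of ribonucleotide reductase (RNR)
    proteins. Aligns query sequences to biochemically characterized Class I
    subclass representatives, projects annotated active-site positions onto
    the query through an explicit alignment coordinate map, and assigns RNR
    class (I alpha, I beta, II) and Class I subclass (Ia-Ie, or novel) from
    diagnostic residue rules: the tyrosyl radical site, the eight
    metal-binding sites of the beta subunit, and the consecutive
    radical-transfer tyrosine pair of the alpha subunit. Includes reference
    curation utilities (dereplication, intein excision, region-of-interest
    trimming, greedy identity clustering), sequence similarity networks,
    neighbor-joining clade placement, discovery of overlooked beta-subunit
    genes in phage genomes, and a seeded synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
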