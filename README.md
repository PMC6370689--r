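# rnrclassify

Rule-based class and subclass annotation of ribonucleotide reductase (RNR)
proteins, for people working with viral and microbial sequence data where
divergent RNRs are routinely misannotated.

RNRs catalyze the rate-limiting step of DNA synthesis and divide into
classes by their radical-generation machinery: Class I (O₂-dependent, a
catalytic α subunit plus a radical-generating β subunit), Class II
(O₂-independent, single-subunit, B₁₂-dependent) and Class III
(O₂-sensitive). Class I further splits into subclasses Ia–Ie by the β
subunit's metallocofactor and tyrosyl radical site. Because inter-class
sequence similarity is low while the functional residues are sharply
conserved, homology pipelines misannotate divergent RNRs — most famously,
phage Class I enzymes labelled Class II because the genome's β subunit was
never annotated. This package implements the residue-level evidence chain
that detects and repairs such cases.

## The method

A query is globally aligned (BLOSUM62, affine gaps 10/1) against
biochemically characterized subclass representatives, and the
representatives' annotated site positions are projected onto the query
through an explicit coordinate map. The diagnostic residues are:

* β subunit: the eight metal-binding sites — six first-sphere ligands
  (sites 1–6; 3 and 6 are invariant His) and two second-sphere residues
  (sites 7–8) — plus the tyrosyl radical site (Y122, *E. coli* R2
  numbering);
* α subunit: the catalytic complement shared with Class II, plus the two
  *consecutive* radical-transfer tyrosines (Y730/Y731, *E. coli*
  numbering) that Class II enzymes lack.

Class calls: full first-sphere coverage → Class I β; catalytic coverage
with the YY pair → Class I α; without it → Class II; insufficient coverage
→ unassigned. Subclass calls match the eight extracted residues against
group-level allowed-residue patterns by exact set membership: a unique
match yields the group's subclass, a complete profile matching no group is
flagged `novel`, ambiguous matches are reported but left unassigned. Mixed
groups are split by the published rules (NrdBz on the radical-site residue
Y vs F/L/V; NrdF on carboxylate conservation at sites 2, 4, 5), and α
subunits inherit the subclass of their genome's unique β partner.

Around the core rules the package provides reference curation
(dereplication, intein excision, functional filtering, region-of-interest
trimming, CD-HIT-style greedy identity clustering), sequence similarity
networks with −log₁₀(E-value) edge scores, neighbor-joining trees with
clade/outgroup queries, β-subunit discovery in annotated phage genomes
(length window 200–500 aa → residue screen → adjacency to the α gene), and
a seeded synthetic-data generator used throughout the test suite.

The bundled subclass representatives are **synthetic stand-ins**:
randomized backgrounds carrying the published diagnostic residues at the
published positions (see `?rnr_references`). Real reference sets can be
supplied via `load_references()`.

## Worked example

Generate a toy phage genome with a hidden β subunit, discover it, and
classify it:

```r
library(rnrclassify)

g <- make_genome(seed = 7)                      # alpha + hidden beta + decoys
cand <- discover_beta(g$genome, "alpha_gene")
cand[, c("protein_id", "length", "passed_residues", "adjacency", "rank")]
#>   protein_id length passed_residues           adjacency rank
#> 1  beta_gene    375            TRUE downstream_of_alpha    1
#> 2 decoy_in_1    215           FALSE          downstream    2
#> 3 decoy_in_2    277           FALSE          downstream    3
#> 4 decoy_in_3    470           FALSE          downstream    4

classify_rnr(stats::setNames(cand$sequence[1], "beta_gene"))
#> <classification> beta_gene: class1_beta / If [CyanoSP]

prof <- extract_profile(stats::setNames(cand$sequence[1], "beta_gene"),
                        rnr_references(), "class1_beta")
metal_residues(prof)
#> metal_1 metal_2 metal_3 metal_4 metal_5 metal_6 metal_7 metal_8
#>     "E"     "E"     "H"     "E"     "E"     "H"     "D"     "D"
```

Four unannotated proteins fall in the 200–500 aa window; only the planted
subunit carries the full first-sphere complement, and it sits directly
downstream of the α gene, so it ranks first. Its extracted metal-site
pattern (E,E,H,E,E,H,D,D) matches none of the classical subclass rows in
full-pattern mode but exactly the Cyano SP row, and it lacks the tyrosyl
radical residue — the signature of the proposed novel subclass If. In
first-sphere-only mode the same profile matches the Ic and Id
representatives, which is why both matching modes are always reported.

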