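---
title: "Rule-based class and subclass annotation of ribonucleotide reductases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based class and subclass annotation of ribonucleotide reductases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnrclassify)
```

## The annotation problem

Ribonucleotide reductases (RNRs) reduce ribonucleotides to
deoxyribonucleotides, the rate-limiting step of DNA synthesis, and are
among the most common genes in lytic dsDNA phage genomes. All RNRs share a
thiyl-radical catalytic mechanism, but the machinery that generates the
radical divides them into classes with very different ecology: Class I
enzymes are O~2~-dependent and split the work between a catalytic α subunit
(*nrdA*/*nrdE*) and a radical-generating β subunit (*nrdB*/*nrdF*);
Class II enzymes are O~2~-independent, single-subunit (*nrdJ*), and require
adenosylcobalamin (B~12~); Class III enzymes are O~2~-sensitive and bear no
usable sequence similarity to the other two. Class I is further divided
into subclasses (Ia–Ie) by the β subunit's metallocofactor, its oxidant,
and whether it carries and uses a stable tyrosyl radical site.

Because overall sequence similarity between classes is low while the
*functional* residues are strongly conserved, divergent RNRs are easily
misannotated by homology pipelines — a cyanophage Class I enzyme can sit in
databases labelled Class II simply because no β subunit was annotated in
the genome. This package implements the residue-level evidence chain that
detects and repairs such misannotations:

1. align a query against biochemically characterized subclass
   representatives,
2. project the representatives' annotated active-site positions onto the
   query through an explicit alignment coordinate map,
3. apply small, auditable residue rules to call the class and subclass, and
4. support the surrounding analyses — reference curation, greedy identity
   clustering, similarity networks, neighbor-joining placement, and
   discovery of overlooked β-subunit genes in phage genomes.

## Diagnostic residues and classification rules

The β subunit binds its (di-)metal cofactor through six **first-sphere**
ligands (sites 1–6; sites 3 and 6 are invariant histidines) supported by
two **second-sphere** residues (sites 7 and 8). Subclasses Ia, Ib and Ie
additionally carry the radical-harboring tyrosine (Y122 in *E. coli* R2
numbering); Ic replaces it with Phe/Leu/Val; Id conserves it without
forming a radical. The α subunit shares its catalytic sites with Class II
enzymes (they are sister lineages) but is distinguished from them by two
*consecutive* C-terminal tyrosines (Y730/Y731, *E. coli* numbering) that
shuttle the radical between subunits.

The calls are therefore:

* **Class I β** — the query displays all six first-sphere sites, each with
  a residue allowed at that site in at least one known group pattern.
* **Class I α** — the shared catalytic complement is intact *and* the
  radical-transfer tyrosine pair is present, with the two tyrosines
  consecutive in query (peptide) coordinates, not merely in alignment
  columns.
* **Class II** — catalytic complement intact, tyrosine pair absent.
* **unassigned** — insufficient coverage. This is a value, not an error.

Subclass assignment matches the eight extracted metal-site residues
against group-level allowed-residue patterns (one row per RNRdb group plus
the Cyano SP clade) by exact set membership — no partial credit:

* a unique full-pattern match yields that group's subclass, preserving the
  "Ia (presumed)" label for groups without characterized members;
* no match on a *complete* eight-residue profile yields `novel` — the
  situation that defines the proposed Cyano SP subclass (If);
* matches to several overlapping rows are all reported but the call is left
  `unassigned`: overlapping patterns (e.g. NrdBh/NrdBn/NrdBza) are resolved
  phylogenetically, which is a separate evidence channel;
* an incomplete profile is `unassigned`, never `novel`.

Two special splits follow the published rules for mixed groups: NrdBz
splits on the tyrosyl radical site (Tyr → NrdBza/Ia; Phe, Leu or Val →
NrdBzc/Ic; anything else unassigned), and NrdF splits on carboxylate
conservation at sites 2, 4 and 5 (all Asp/Glu → NrdFb/Ib; none → NrdFe/Ie;
mixed → unassigned). "Carboxylate" is taken as {D, E}, the standard
biochemical reading. α subunits, which cannot be subclassed from primary
sequence, inherit the subclass of their genome's β subunit; an α pairing
with zero or with several β subunits is excluded from downstream analysis.

A separate first-sphere-only matching mode (sites 1–6) covers queries whose
second-sphere columns fail to align; the package reports both modes and
does not arbitrate between them, because the trade-off between a
first-sphere match and a full-pattern mismatch is itself biological
evidence, not a tie to be broken numerically.

## Alignment and coordinate mapping

All alignments are affine-gap BLOSUM62 alignments (Needleman–Wunsch/Gotoh,
delegated to `Biostrings::pairwiseAlignment`). Gap penalties are open 10 /
extend 1 — the common half-bit-matrix convention — and are exposed in
`align_params()`; the downstream rules depend only on site columns, which
are robust to small penalty changes at the conservation levels involved.
Unknown letters are recoded to X (configurable to a hard error); X scores
neutrally (0) and never satisfies a residue rule, because a residue rule
asserts the identity of a specific amino acid.

Site projection is formalized as a `PositionMap`: the partial, strictly
increasing map from 1-based ungapped reference positions to 1-based
ungapped query positions, undefined where the query has a gap. Rather than
building an anchored multiple alignment and hand-curating site columns,
`align_to_profile()` builds a star of pairwise query–reference alignments
and `extract_profile()` lets the **highest-scoring reference of the
requested role decide each site's value** — including absence, when its
site column holds a query gap. Lower-scoring references cannot overrule the
best one; if one of them maps a site to a different query position the site
is flagged `conflict` for auditing. This reproduces the observable contract
of a site-anchored profile alignment (sites map; disagreements are flagged;
the best-aligned representative wins) while staying deterministic and
avoiding a heuristic MSA step that the rules never consume. A query in
which every site column is a gap is reported as unalignable, not an error.

## Reference data

The package bundles one β and one α representative per subclass (Ia–Ie)
plus one Class II representative, with curated site annotations in the
representatives' published coordinates (e.g. D85/E116/H119/E205/E239/H242
with S115/D238 and Y122 for the Ia β in *E. coli* NrdB numbering). The
*sequences* are synthetic stand-ins — randomized backgrounds carrying every
annotated residue at its published position — so the package builds and
tests without network access; they are clearly labelled synthetic and are
not the biological proteins. Consequences of this choice are discussed
under *Limitations*. The α/Class II catalytic-site list
(C225/N437/C439/E441/C462 plus Y730/Y731) is a curator-supplied fixture:
the full published supplementary enumeration is not reproduced here, and
the loader treats it as curated input, not ground truth. Both tables
round-trip through plain TSV + FASTA (`load_references()`,
`write_references()`, `load_patterns()`, `write_patterns()`), with
integrity checks that every annotated residue is literally present at its
stated position.

## Curation

* `dereplicate()` removes exact duplicates and substring matches, keeping
  the longest of each redundant set (ties broken lexicographically by id).
* `remove_inteins()` automates manual intein excision as the removal of
  contiguous query-only insertions of at least `min_insert` alignment
  columns (default 50 — inteins are typically hundreds of residues, and 50
  stays safely above ordinary indel noise). Excision refuses and flags for
  manual review if an insertion boundary abuts a mapped site residue, or if
  re-extraction after excision would change any site residue; the package
  never silently cuts into functional sequence.
* `filter_functional()` drops sequences lacking essential catalytic
  residues (likely non-functional): for β roles the six first-sphere sites
  with pattern-allowed residues, for α/Class II the full catalytic
  complement with exactly the reference residue.
* `trim_roi()` restricts sequences to shared regions of interest before
  phylogenetic work: the combined α + Class II region (N437–S625), the
  α-only region (from C225, dropping the mobile N-terminal ATP-cone
  domain; the C-terminus is kept), and the β region (W48–Y356, excluding
  ATP-cone-like N-termini and fused glutaredoxin C-termini). The trim is
  iterated to a fixed point so it is exactly idempotent even when an
  alignment boundary is ambiguous by a residue.
* `greedy_cluster()` is CD-HIT-style greedy clustering: longest sequence
  first (ties by id), each sequence joins the first representative reaching
  the identity threshold under the coverage constraint, otherwise seeds a
  new cluster. Identity is counted over the shorter sequence (the CD-HIT
  convention; an alignment-length denominator is also provided), coverage
  as the fraction of alignment columns pairing residues in both sequences.
  The analyses use thresholds 0.70/0.75/0.80 with coverage 0.8 for
  full-length sets and 1.0 for short trimmed regions, and 0.90 for network
  representatives. A `passthrough` flag keeps designated sets (e.g. the
  focal divergent clade) unclustered.

## Networks and trees

`build_ssn()` collapses sequences into 90%-identity representative nodes
and draws an edge between two nodes when the significance of their local
alignment reaches the minimum alignment score (default 90). The edge score
is the −log~10~ E-value of the optimal Smith–Waterman score under
BLOSUM62, using the standard gapped Karlin–Altschul constants λ = 0.267,
K = 0.041 and search space m·n; the constants are fixed and documented so
the threshold is interpretable. The historical "fraction" parameter of
network tools is recorded as provenance only — it has no published
closed-form meaning and is not functional here. Connected components
(`ssn_components()`) report sizes and singleton counts, the statistics used
to describe how a divergent clade fragments.

`nj_tree()` is standard neighbor joining (via `ape::nj`) on a validated
symmetric, zero-diagonal, non-negative distance matrix; on additive
matrices the tree metric reproduces the input exactly, which is the
package's testable stand-in for likelihood tree construction — the claims
the pipeline supports are topological (clade membership, outgroup
placement), not likelihood values. `clade_query()` answers those questions
on unrooted trees: whether a focal set of leaves forms a split, and the
label composition of the adjacent subtrees (e.g. "the focal clade is the
outgroup of the branch holding groups G and H").

## β-subunit discovery in genomes

`discover_beta()` composes three steps over an ordered
`genome_protein_set`: (i) `length_filter()` keeps unannotated
("hypothetical") proteins of 200–500 residues inclusive — β subunits are
typically 350–400 aa, and the window is deliberately widened so divergent
subunits are not excluded; (ii) `residue_screen()` keeps candidates whose
β-role profile shows every first-sphere site with a pattern-allowed
residue; (iii) `adjacency_rank()` orders candidates: residue-passing first,
then the gene directly downstream of the α subunit (the typical operonic
arrangement), then by gene distance, ties by id. "Directly downstream" is
read as the next coding gene in reading order on the α's strand; strand
awareness is configurable (`same_strand = FALSE`) since the source
procedure does not state how strand was handled. Coordinates follow the
GenBank 1-based inclusive convention.

## The synthetic-data generator

Every pipeline stage is tested against generated data with known ground
truth:

* `make_beta()` plants a group's metal-site residues (sampled from the
  allowed sets) and a group-appropriate tyrosyl-radical residue at the Ia
  scaffold's annotated positions, inside background mutated at a
  configurable substitution rate (default 0.05 — enough divergence to
  exercise the alignment without threatening site columns). Noise never
  touches planted sites unless an explicit `knockout` switch corrupts
  them; this separates "divergent" from "non-functional" in tests.
* `make_alpha()` does the same for the α scaffold, with a switch that
  mutates the second transfer tyrosine to Phe, producing a Class II mimic
  under the class rules.
* `make_family_set()` evolves families from a common root by
  substitution-only divergence, with rates inverted analytically from the
  identity targets (agreement probability (1−r)² + r²/19, the second term
  counting convergent substitutions). Realized within-family identities
  land within about three percentage points of target; at low identity
  (~40%) optimal alignment recovers one or two points of spurious matches
  above the planted value, a known measurement bias.
* `make_genome()` lays out a toy phage genome: annotated filler, an
  annotated α gene, the hidden β at a controlled offset, and hypothetical
  decoys. Defaults mirror the discovery study conditions: four
  hypothetical candidates inside the 200–500 window (three decoys plus the
  true β), forward strand, β directly downstream of α.

All generators are reproducible from `(arguments, seed)` and leave the
caller's RNG state untouched.

What the generator does **not** emulate: insertion/deletion evolution
along a tree (indels appear only via the planted-insert mechanism),
compositional bias (backgrounds are uniform over the 20 residues;
BLOSUM-marginal frequencies would be the realistic alternative), true
inter-subclass homology between the bundled representatives, and genome
features like overlapping or nested genes. Passing tests therefore
demonstrate the correctness of the rules, coordinate mapping and ranking
logic — not the sensitivity of BLOSUM62 alignment to realistically
divergent natural sequences, which is bounded by the alignment engine, not
by this package's logic.

## Numerical choices and degenerate inputs

* Deterministic tie-breaks throughout: reference order by alignment score
  then id; clustering order by length then id; NJ tie-breaking as
  implemented in `ape`; component ordering by smallest member id.
* Distance-matrix validation: symmetry to 1e-9, zero diagonal,
  non-negativity; additive recovery asserted to 1e-9.
* Empty results are values: an empty candidate table, an unalignable
  profile, an empty trimmed sequence ("" signals unalignable-in-ROI) —
  errors are reserved for malformed inputs (bad coordinates, unknown
  groups, residue/position disagreements, which name the offending row or
  position).
* Suite problem sizes: 10,000 random residue 8-tuples against the
  brute-force membership oracle; 1,000 random additive matrices (4–8
  taxa); 200 random clustering sets of up to 8 sequences; 100 synthetic
  genomes for end-to-end discovery. These sizes make the stochastic checks
  effectively exhaustive for the decision logic while keeping the default
  suite inside a few minutes.

## Limitations

* The bundled representatives are synthetic stand-ins. All rule logic,
  coordinate mapping, curation and discovery behavior is fully exercised,
  but checks anchored to real database accessions (e.g. re-deriving a
  published genome's candidate count from its actual record) require the
  user to supply the real sequences via `load_references()`; the packaged
  fixtures cannot stand in for them.
* Because the synthetic representatives are mutually non-homologous,
  cross-representative conflict flags on natural data (where
  representatives genuinely align to each other) will be rarer and more
  informative than on the fixtures.
* The NJ tree is a deterministic stand-in for approximate-ML construction;
  only topology-level conclusions should be drawn from it, and no
  bootstrap support is computed.
* Intein excision is an automated approximation of expert manual editing;
  it is conservative (refusal rules above) and always reports excised
  coordinates, but unusual intein architectures (e.g. inteins inserted
  exactly at a diagnostic site) are flagged for manual review rather than
  resolved.
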