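---
title: "Methods: comparative structural analysis of plant mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural analysis of plant mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomosaic)
```

## The problem

Plant mitochondrial genomes are large (hundreds of kilobases), mostly
non-coding circular molecules whose structure is shaped by repeated
sequences. Near-identical repeat copies recombine with each other; the
products are inversions, duplications and deletions, multipartite genome
configurations, and — at finer scale — intron-length polymorphisms where a
short direct repeat pair has collapsed the region between its copies.
`mitomosaic` provides the analyses that a comparative study of such
genomes runs after assembly and annotation:

* self-comparison **repeat detection**, with direct/inverted orientation
  and the conventional size tiers (small `< 100` bp, medium `100–1000` bp,
  large `>= 1000` bp);
* **gene-order rearrangement distances** between genomes by the
  double-cut-and-join (DCJ) model;
* scanning of orthologous intron alignments for **deletions flanked by
  short direct repeats** — the footprint of repeat-mediated collapse;
* **pseudogene-fragment detection** in intergenic spacers;
* **shared and anonymous sequence accounting** between genome pairs;
* **dS/dN estimation** by Nei–Gojobori (1986) counting and conversion to
  absolute substitution rates per site per billion years;
* classification of long reads spanning a repeat pair as **parental or
  recombined**, the direct read-level evidence for recombination.

Each stage is exercised on synthetic circular genomes with planted ground
truth (see *The synthetic generator* below) and on curated published
tables shipped under `inst/extdata/`.

## The alignment kernel

All homology searches go through one seed-and-extend kernel
(`find_seeds()`, `extend_seed()`, `align_hits()`), which emulates a
nucleotide BLAST search while remaining fully deterministic:

1. exact $k$-mer seeding on both strands (`N` never matches anything,
   including `N`);
2. ungapped x-drop extension of each seed (matches $+2$, mismatches $-3$,
   x-drop 20 by default), with per-diagonal pruning so a long homologous
   diagonal costs one extension, not one per seed;
3. an exact affine-gap local realignment (Gotoh; gap of length $L$ costs
   $5 + 2L$) of the extended window, anchored to contain the seed.

Instead of an e-value cutoff — which depends on database size — hits are
filtered by **minimum length** (default 20 bp) and **minimum identity**
(default 0.80), the deterministic equivalent of the usual
"length > 19 bp, identity > 80%" repeat-reporting convention. An exact
full Smith–Waterman oracle (`local_align()`) is exposed for small
problems; the test suite property-checks the seed-and-extend path against
it and cross-checks the DP kernel itself against
`Biostrings::pairwiseAlignment`.

Two numerical choices deserve a note. The gapped realignment is skipped
for hits whose ungapped extension is already perfect — a gapped variant
cannot help a 100 %-identity hit by more than boundary noise, and this is
where nearly all the time went on genome-scale scans. And the default
word size for genome self-comparison is 13, not the 7 used for small
search spaces: at $k = 7$ a 100 kb self-comparison yields on the order of
$10^9$ chance seeds. Every detector of this package targets homologies of
at least 80 % identity and 20 bp, which at genome scale always contain a
13-mer exact match in practice; the pseudogene scan, whose search spaces
are a gene against a genome, keeps $k = 7$. Both are configurable.

## Repeat detection on a circle

`find_repeats()` aligns the genome against itself. Circularity is handled
by doubling the sequence, capping hits at the genome length, and
deduplicating pairs modulo the genome length; the trivial self-match
(and its doubled echoes) is removed by excluding the corresponding
diagonals before extension. Each surviving hit becomes a repeat pair with
the two copies in canonical (lexicographic) order, an orientation — same
strand = direct repeat (DR), opposite = inverted repeat (IR) — and a size
class. Nested and overlapping pairs with distinct coordinates are all
retained, matching the "unique start and end coordinates" accounting
convention of published repeat tables. `summarize_repeats()` counts
coverage as the union of all repeat-covered positions over both copies
(switchable to first-copy-only accounting), since published totals do not
state which convention they use.

The size tiers use `large >= 1000 bp` and `medium [100, 1000) bp`: the
1000 bp boundary is claimed by both tiers in the conventional wording,
and the explicit `>=` inequality wins.

A worked example ships with the package: `mt_repeat_table()` returns the
21 annotated repeat pairs (> 100 bp) of the *Sophora japonica*
'JinhuaiJ2' mitogenome (GenBank MG757109). Classifying the printed sizes
reproduces 20 medium + 1 large (2,160 bp), and calling orientation from
the printed coordinate directions (descending second copy = IR)
reproduces the printed type column for all 21 rows — 8 DR and 13 IR.
Note one borderline row: pair *Ru* is printed at 79.86 % identity,
just below the 80 % reporting filter stated alongside the same table.
The synthetic default spectrum plants all 21 pairs as printed, so a scan
at the default `min_identity = 0.80` recovers 20 of them; lowering the
threshold recovers the borderline pair too. The package applies the
configurable threshold and leaves the discrepancy visible rather than
resolving it.

## DCJ distances

`extract_gene_order()` turns an annotation into a signed circular gene
order (sign = strand). Trans-spliced genes contribute one marker at their
first exon's fragment; multi-copy genes are removed from both orders
before comparison (policy `drop-all`, with `keep-first` available),
because the DCJ distance as implemented assumes single-copy content.

For circular single-chromosome genomes the DCJ distance is
$d = N - C$, where $N$ is the number of shared genes and $C$ the number
of cycles in the adjacency graph. The implementation walks the orbits of
the composition of the two adjacency involutions; each graph cycle with
$2k$ extremities splits into exactly two orbits of size $k$, so
$C = \text{orbits}/2$. The distance is 0 exactly when the orders agree up
to rotation and whole-genome reflection — the orientation of a circle is
arbitrary. An independent exhaustive oracle (`dcj_distance_bfs()`,
breadth-first search over all DCJ moves through intermediate
multi-circular genomes, implemented in C++) verifies the formula: the
tests check every signed circular permutation up to $n = 6$ genes and
random samples at $n = 7$–8, plus the metric axioms and the
planted-inversion property ($k \le 4$ disjoint inversions of a 30-gene
circle cost exactly $k$).

Published pairwise rearrangement counts for real mitogenomes were
produced with a different tool whose rearrangement model is not stated;
distances on real genomes are therefore demonstrated, not asserted
against printed values.

## Repeat-mediated intron deletions

`find_deletion_blocks()` reports maximal per-taxon gap runs in an
orthologous intron alignment (runs separated by fewer than `merge_gap`
columns are merged, default 10), measured in reference bp — columns where
at least one other taxon retains sequence — and filtered at `min_del`
(default 50 bp). A gap shared by every taxon is alignment trimming, not a
deletion, and is never reported.

`edge_repeat_search()` then looks for a direct repeat pair with one copy
at each edge of the deletion in a retaining taxon. "Precisely at the
edge" is operationalized as an *edge distance*: a copy covering or
abutting the edge position scores offset 0, and offsets run inward
(default window 5 bp; set `window = 0` for the strict reading). The
tolerance exists because a repeat-mediated collapse has an intrinsic
gap-placement ambiguity of one repeat length: the surviving copy in the
deleted lineage can be aligned against either edge copy, shifting the
apparent block by the repeat length. Matches are exact by default
(`max_mismatch = 0`), reflecting that the biologically observed edge
repeats at 13–15 bp are exact; only direct repeats are searched unless
`inverted = TRUE`. Candidates are enumerated exhaustively over the edge
windows, so an empty result is a certificate that no qualifying pair
exists at those parameters.

## Pseudogene fragments and sequence sharing

`scan_pseudogenes()` aligns each functional gene against the genome and
reports hits lying wholly in intergenic space (outside genes including
introns, and outside tRNA/rRNA features). Detection is two-phase: a
sensitive pass with thresholds relaxed by 10 identity points and 8 bp —
so fragments split by mismatch clusters during extension are still
collected — followed by an exact local realignment of the padded,
intergenic-clipped candidate region, to which the real thresholds
(default 28 bp and 92 %, the observed envelope of such fragments) are
applied. Score-optimal alignments that run a few chance-matching bases
past the fragment are end-trimmed (bounded trim budget of 20 bp per end)
before thresholding; trimming never selects an interior core, so a
genuinely diverged fragment cannot sneak in through a short
high-identity stretch. `flag_repeat_association()` marks hits contained
in (default) or overlapping repeat copies — containment because the
biological claim is that fragments sit *inside* recombining repeats.

`shared_content()` estimates the mtDNA amount shared by a genome pair as
the interval union of all qualifying hits on each genome (defaults:
min length 100 bp, min identity 0.70, both strands). This replaces
collinear-block computation with a deterministic coverage accounting;
the thresholds are recorded in the output. Raising either threshold can
only shrink the reported coverage (a tested monotonicity).
`anonymous_content()` is the complementary arithmetic: genome length
minus the union of known-content intervals.

## Substitution rates

`ng86_pairwise()` implements classic Nei–Gojobori counting: synonymous
site counts $S$ per codon as the synonymous fraction among non-stop
single-nucleotide neighbours at each position (so $S + N = 3$ for every
sense codon, verified exhaustively over all 61), difference counts with
equal-weight averaging over the mutational pathways of multi-hit codons
(pathways through stops excluded, with a documented fallback when all
are blocked), and the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. Proportions at or above $3/4$
are flagged saturated and yield `NA`. Codons containing gaps, `N`s or
stops in either sequence are masked; fewer than 30 usable codons draws a
warning. This counting estimator stands in for maximum-likelihood
codon-model fitting, which is out of scope here; the absolute-rate
normalization — dividing a per-branch substitution estimate by the
branch age, `absolute_rate(d, age_myr) = d / (age_myr/1000)` per site
per billion years, with ages supplied by the user — is reproduced
exactly.

Parameter recovery is tested against an explicit-event simulator
(`simulate_codon_pair()`): Poisson numbers of synonymous and
nonsynonymous events at expectations $d_S \cdot S$ and $d_N \cdot N$,
each event a uniform draw among the eligible single-nucleotide changes
of the current sequence. The recovery checks compare the estimate with
the *realized* event rate recorded by the simulator, which isolates the
estimator's bias from the generator's sampling noise; at 10,000 codons
over $d_S \in \{0.05, 0.2, 0.5\}$, $\omega \in \{0.1, 0.5\}$ both rates
come back within 10 % (and mean bias within 5 % across 20 replicates at
5,000 codons).

## Recombination evidence from long reads

A read *spans* a repeat when the repeat sequence aligns inside it over
essentially its full length (10 bp slack per end for boundary noise)
with at least `min_flank` bases on both sides (default 500 bp; at least
100). For each spanning read, `classify_spanning_reads()` aligns each
flank against the corresponding genomic context of both copies —
orientation-corrected for inverted repeats — and assigns it to the
context with higher identity when the margin exceeds 2 %; otherwise the
flank is ambiguous. Both flanks unambiguous and pointing to different
copies' contexts = `recombined`; same copy = `parental`; anything else =
`uninformative`. The reported statistic is recombined over spanning with
a Wilson 95 % interval, the "2 out of 6 reads" form of read-level
recombination evidence. The flank length and margin defaults are this
package's choices; the source analyses do not state theirs, so published
spanning-read counts are treated as qualitative anchors only.

Tested properties: zero recombined calls on error-free reference reads;
call stability under 1 % uniform read error at 500 bp flanks; estimated
recombined fraction within the binomial envelope of the planted fraction;
`uninformative` when the two copies' contexts are themselves duplicated.

## The synthetic generator

`generate_genome()` realises a `genome_blueprint()`: i.i.d. background
bases at the requested GC (0.454 by default, the typical GC of these
genomes), a plant-mitochondrial-style gene complement (~30 protein genes,
six with cis-spliced introns, two trans-spliced as separated fragments,
three rRNAs, five tRNAs), planted repeat pairs, and planted pseudogene
fragments, all with exact coordinates in a machine-readable truth set.
The default scale is 100 kb — a 5× scale-down that keeps the full gene
complement and the full default repeat spectrum (the 21 printed pairs,
sizes/orientations/identities as published) while keeping a full scan
under ~20 s; a paper-scale genome is just
`genome_blueprint(length = 484916L)`. Packing is deterministic-robust:
repeats are planted first into the empty circle (largest first), genes
are packed largest-first as spacer+gene blocks whose spacer shrinks to
zero under pressure, and pseudogenes take remaining gaps; a blueprint
that genuinely does not fit raises an explicit packing error. Mutating a
copy to a target identity floors the mismatch count, so realized identity
is never below the requested value.

Companion generators: `derive_genome()` (substitutions plus unique
insertions, with the expected shared fraction available in closed form),
`evolve_gene_order()` (disjoint, non-adjacent segment inversions, so $k$
inversions cost exactly $k$ DCJ operations),
`simulate_reads()` / `simulate_spanning_reads()` (uniform circular
sampling; recombined reads built by swapping the right-flank context
across the designated repeat pair; per-read truth labels) and
`simulate_intron_alignment()` (deletion block with planted edge repeats
at requested inward offsets, or screened repeat-free edges for
negatives). Everything is seeded and byte-reproducible.

What the generator deliberately does **not** emulate: higher-order base
composition, mutation spectra, indel-containing repeats, chimeric or
length-dependent read-error models, and genuinely unknown (horizontally
transferred) sequence. Passing the planted-recovery suites therefore
demonstrates correctness of the detectors under threshold-driven,
substitution-only divergence — not performance on real reads or real
repeat families. In the default blueprint the planted feature classes are
kept non-interfering (pseudogene fragments below 100 bp, so they never
double as medium repeats); dedicated blueprints cover the full 28–182 bp
pseudogene envelope.

## Composition accounting

`partition_genome()` partitions a genome exactly into coding (exons plus
tRNA/rRNA), intron, and intergenic space with precedence
coding > intron > intergenic, and reports one-decimal percentages with
half-up rounding (the convention of printed tables; base R's
`round()` is half-even). "Coding" is defined as gene bp minus intron bp —
the definition under which the published totals of the genomes in
`mt_genome_traits()` are internally consistent — and
`composition_from_totals()` applies the same identity directly to
published totals: for the 484,916 bp *S. japonica* mitogenome it returns
86.7 % intergenic, 5.8 % intron, 7.5 % gene-coding and 6.1 %
protein-exon, matching the printed values exactly.

## Orchestration, problem sizes, limitations

`run_pipeline()` chains the stages over a config list, skips stages whose
inputs are missing (with a logged reason), and optionally writes every
report as TSV with a parameter-recording header; reruns are
byte-identical. There is deliberately no shell executable — the package
is a library, and the functions plus this vignette are its interface.

The test suite runs its scans at 8–50 kb genome scale, 10 k codons, and
gene orders up to $n = 8$ for the exhaustive oracle (one shared BFS per
gene count — the $n = 8$ state space has ~2 million matchings); these
sizes make the full suite complete in a few minutes while every check is
at full method fidelity. Known limitations: the repeat finder's default
word size trades away sensitivity below ~80 % identity at the shortest
lengths; DCJ handles single-copy circular content only; NG86 is a
counting estimator and will under-correct at high divergence where a
codon model would not; and the sharing estimate is coverage-based, not
synteny-aware, so highly repetitive genomes can share coverage without
sharing arrangement.
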