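---
title: "Profile-HMM-guided gene-targeted assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-HMM-guided gene-targeted assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmasm)
```

## The problem

Shotgun metagenomes sample whole communities, but the genes a study
actually cares about — phylogenetic markers such as ribosomal protein L2
(*rplB*), or functional markers such as copper nitrite reductase (*nirK*)
and nitrogenase reductase (*nifH*) — are a vanishing fraction of the
reads.  Bulk assembly followed by gene calling recovers few of them, and
mostly as fragments.  `hmmasm` instead assembles *only* the target genes,
steering the traversal of the read de Bruijn graph with a profile hidden
Markov model (HMM) of the target protein family, so assembly and
annotation happen in a single step.

## The combined assembly graph

The reads are decomposed into nucleotide k-mers (`k = 45` by default,
always a multiple of 3) and counted in canonical form — the
lexicographically smaller of a k-mer and its reverse complement — so both
strands are queryable.  The de Bruijn graph is never materialised: a
vertex exists iff its k-mer passes the abundance cutoff (`min_count = 1`
by default), and edges are implied by (k−1)-overlap.

A profile HMM over the 20 amino acids supplies the guidance.  Searching
in protein space means walking *three* nucleotide vertices at a time: a
codon step from one k-mer exists only if each of the three intermediate
single-base shifts is itself present at the cutoff.  The search state is
a **combined vertex** — a pair of a k-mer and an HMM state (match M,
insert I, or delete D at a model column).  Delete states advance the
column while carrying the k-mer of the last emitting state forward, which
preserves the context needed to generate subsequent codon steps.

Edge weights are the log of transition times emission probability, with
emissions normalised to a background (null) model:

* into a match state: `log t + log(e_j(a) / bg(a))`,
* into an insert or delete state: `log t` (insert emissions are set equal
  to the background, so their log-odds term is identically zero).

Because normalised match emissions can exceed 1, raw weights are not
monotone.  For search, the per-column maximum `c_j = max_a log(e_j(a)/bg(a))`
is subtracted from every edge entering column *j*'s match **or delete**
state (the M→M, I→M, M→D, D→M, D→D edges).  All modified weights are then
strictly negative, path scores decrease monotonically, and the argmax
path between fixed endpoints is unchanged: raw and modified scores of any
complete path differ by the path-independent constant `Σ c_j` over the
columns consumed (a property the test suite asserts to 1e-9).  Contig
quality is always reported from the *unmodified* weights, in bits.

## Model construction

Models are built from a trusted seed alignment per gene, or read from a
HMMER3 ASCII file.  Construction differs deliberately from generic
remote-homology defaults, because the assembler targets close homologs:

* **No sequence weighting** — every seed sequence counts once.
* **Transition priors** — posterior means
  `(count + w·prior) / (total + w)` with prior strength `w = 1`;
  delete→match and insert→match prior means are 0.95 and delete→delete /
  insert→insert are 0.05.  With sparse seed data this strongly
  discourages the long nonproductive insert/delete excursions that
  uniform priors permit.  Remaining transitions use uniform prior means.
* **Match emissions** — observed counts with a uniform Laplace
  pseudocount of 1/20 per residue.  Dirichlet mixture priors would buy
  little here and are deliberately out of scope; the pseudocount is a
  parameter for anyone who disagrees.
* **Background** — a fixed Swiss-Prot-style amino-acid composition
  (`aa_background()`); a uniform background can be supplied instead.
* Columns with gap fraction below 0.5 (`symfrac`) become match columns.
* Plan-7 legality: I→D and D→I events, which cannot occur in the state
  graph, are dropped during counting.
* Stop codons translate to a sentinel with probability 0 (−∞ weight), so
  no path ever reads through a stop.

Because starting vertices sit anywhere in the model, a **reversed model**
is built from the column-reversed seed alignment; leftward search runs
against it, with forward column *j* mapping to reversed column
`L − j + 1`.

## Starting vertices

All overlapping peptide k-mers (length `k/3`, 15 by default) of a set of
aligned reference proteins are hashed to their (gene, model column); the
reference set may be larger and looser than the HMM seed.  Windows are
indexed only when their residues occupy *consecutive match columns* with
no intervening insert-column residues.  Reads are translated in all six
frames and scanned once for all genes together; every exact peptide
match yields a starting k-mer, re-oriented to the coding strand and
deduplicated on (k-mer, gene, first column).  A stop codon inside a
window simply produces no hit.

## Search

From each starting vertex, A* search runs rightward under the forward
model (from the seed's last column) and leftward under the reversed model
(from the mirrored first column).  The heuristic at a vertex is the score
of the best conceivable completion: the most likely transition into the
next match column plus the best all-match continuation to the model end,
computed once per model by suffix sums.  Under the modified weights the
argmax emission cancels `c_j` exactly, so each heuristic step contributes
only its transition log.  The heuristic is an upper bound on any
all-match completion; a delete-heavy completion could in principle exceed
it for pathological transition values, so the test suite audits
`h(v) ≥ best completion` by exhaustive enumeration on toy instances and
fails on any violation rather than tolerating it silently.

Search bookkeeping per partial path: the modified score `g`, the raw HMM
score, and the number of openings since the raw score last improved.  A
popped vertex whose raw score has stagnated for more than `prune`
openings (default 20; negative disables) is discarded — this is what
terminates searches that run off the end of covered sequence into
background k-mers.  If the open set empties before a goal (terminal
column match/delete state) is reached, the path to the best-raw-score
intermediate vertex is returned and flagged *partial*; partial contigs
still flow into filtering.  Ties in the open set break on
(f, then raw score, then insertion order), making every search
deterministic.

Best paths found earlier in a run are cached per gene and direction:
a vertex on a cached path opens only the next cached vertex, and a
search whose start lies on a cached path follows it directly.  The test
suite asserts cache soundness (identical contig sets with and without
the cache).

The seed's own emissions are credited neither to the left nor the right
search (`g = 0` at the start vertex); scores during search only rank
alternatives within that search, and the final contig is rescored from
scratch: a Viterbi pass over the translated contig under the raw weights,
with model-local entry (the first residue at column *j* is charged the
`M_{j−1}→M_j` transition) and free exit.  Rescoring is therefore a
function of the contig sequence alone, independent of which seed produced
it.

## K best paths

To explore microheterogeneity, a modified Yen's enumeration returns up to
K ranked paths from one starting vertex.  Spur searches branch only at or
after the point where a path branched from its parent (Lawler's
observation), with the parent paths' next edges banned and the root
prefix's vertices excluded.  Two filters keep the ranking informative:
a candidate consumes a rank only if it contains at least one edge absent
from all lower ranks **and** at least one nucleotide k-mer absent from
their union.  Candidates failing either filter are not ranked but still
seed further spurs, so the accepted sequence equals a brute-force
enumeration of all simple start→goal paths in score order passed through
the same greedy filters — the property the acceptance tests assert
against exhaustive enumeration.  The new-kmer filter is evaluated on
nucleotide k-mers (per-direction); a `max_spur_attempts` guard
(default `100 K`) bounds worst-case exploration.  When K > 1 in
bidirectional assembly, ranked alternatives in each direction are spliced
against the best path of the opposite direction and deduplicated.

## Post-processing

Contigs are collapsed to unique nucleotide sequences, filtered at
≥ 300 nt and ≥ 50 bits (both configurable), and clustered by complete
linkage on amino-acid distance at 99% identity, keeping the longest
member (ties: higher bit score, then id) as representative.  Identity is
computed in model-column space — every contig's residues already sit in
model coordinates, so no pairwise aligner is needed and the computation
is exactly reproducible.  The denominator is the number of overlapping
model columns where at least one contig has a residue; mutual-gap
columns are not compared; disjoint spans score 0.

Coverage is estimated without read mapping: all representative-contig
k-mers are indexed canonically, and each read k-mer occurrence
contributes `1/m` to each of the `m` contigs containing it, so shared
regions are never double-counted and split counts sum exactly to the
number of matched occurrences (asserted in the tests).  A contig's
coverage is the mean over its k-mer positions.  Relative gene abundance
is the ratio of reads covering ≥ 1 k-mer of the gene's contigs to reads
covering ≥ 1 k-mer of the single-copy *rplB* contigs; *rplB* against
itself is 1 by construction.  OTU tables at 95% identity weight each OTU
by the summed mean coverage of its member contigs.  Chimera screening is
delegated to external tools: the pipeline writes the query/reference
nucleotide FASTA layout such tools consume and ingests a tab report to
drop flagged contigs.

## The synthetic-community generator

Real validation datasets for this kind of tool are hundreds of gigabases;
the package instead ships a generator whose fixtures make every claim
testable end to end at desk scale.  Proteins evolve from a random
ancestor by i.i.d. substitution (uniform replacement, no indels by
default, so families are trivially aligned); genes are back-translated
with uniform synonymous codon choice; genomes embed each gene in 300 nt
of uniform random background; reads have uniform starts, equiprobable
strands, i.i.d. substitution errors, and a manifest recording ground
truth.  The named fixtures:

* **clean** — two families (named rplB and nirK), two planted variants
  each (110 aa, so full-length contigs comfortably clear the 300 nt
  filter), 30× coverage, error-free 100 nt reads.  The pipeline must
  recover every planted gene full length at 100% nucleotide identity.
* **two_haplotype** — one gene in two haplotypes that differ only inside
  a 21-codon interior block (identical codons elsewhere), with the seed
  family containing descendants of both so neither is favoured; the
  K-paths search from one shared starting k-mer must recover both.
* **shared_kmer** — two diverged variants sharing one exact 33 nt run:
  a cross-variant join is assemblable when `k = 30` (run ≥ k) and
  impossible when `k = 45` (no read k-mer spans the junction).  This is
  the k-mer-length/chimera trade-off in miniature.
* **low_coverage** — 0.5× coverage, guaranteeing zero-coverage gaps and
  exercising search exhaustion and partial-contig flagging.

What the generator does **not** emulate: quality-dependent or indel
errors, GC and amplification bias, repeat structure in the background,
strain abundance skews, and real inter-family sequence similarity.
Passing these fixtures therefore demonstrates correctness of the
algorithms under their stated models, not field performance on soil
metagenomes.

## Numerical and design choices

* Problem sizes: fixtures use 110 aa genes, ~1100 reads, and toy
  search instances use models of L ≤ 10 over graphs of a few dozen
  k-mers — small enough that brute-force enumeration is a practical
  oracle for optimality, admissibility, and ranked-path checks.
* Exact-hash counting is the default backend for transparency; the
  counting Bloom filter (4-bit saturating counters, polynomial rolling
  hashes with a fixed published seed) is an option for memory-bound
  runs.  Its contract is one-sided: never undercounts, bounded
  false-positive rate, checked against the exact backend in tests.
* Probability-zero tokens (`*` in HMMER3 files) parse to −∞ log-odds and
  simply make states unreachable.
* `cutree` at `h = 1 − threshold + 1e-9` keeps boundary-identity pairs
  (exactly at the threshold) inside one cluster despite floating point.
* Contigs are identified by (gene, seed k-mer, first column); outputs are
  sorted by id, and duplicate collapse keeps the lexicographically
  smallest id, so whole-run outputs are byte-identical across repeats
  and thread counts.
* Reads shorter than k after quality trimming contribute no k-mers and
  are dropped with a logged count.

## Limitations

The assembler requires reference alignments for both model building and
start finding: families with no reference peptide of length k/3 shared
with the sample are invisible.  Identity-in-model-space slightly
understates identity for contigs whose alignments disagree at insert
placements.  The per-direction K-paths combination enumerates left and
right alternatives against the opposite best path rather than the full
cross product.  Pure-R data structures cap practical graph sizes well
below the hundreds of gigabases the underlying method targets in
compiled implementations; the algorithms, not the constants, are the
contribution here.

## A worked miniature

```{r example, eval = FALSE}
fx <- make_fixture("clean", tempfile("community"), seed = 1)
res <- run_pipeline(fx$dir, tempfile("out"), k = 45)
res$abundance
#>      gene read_hits relative_abundance
#> nirK nirK       221          0.9208333
#> rplB rplB       240          1.0000000
```

Both planted families are recovered as full-length representatives
(see `<out>/rplB_nt.fasta`, `<out>/rplB_contigs.tsv`), and *rplB*
normalises its own abundance to 1.
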