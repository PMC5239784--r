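---
title: "Methods: joint VDJ annotation, clonal clustering, and SHM analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint VDJ annotation, clonal clustering, and SHM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjlineage)
```

## Scope and model

`vdjlineage` annotates B-cell receptor heavy-chain reads against germline
V/D/J databases, clusters clonally related reads, assembles rooted
multifurcating lineage trees, and refines junction annotations using a
model of TDT-mediated N-nucleotide insertion. The guiding assumption is
that annotation and lineage inference are one problem: the least mutated
member of a clonal family is the most reliable witness of the original
recombination event, so its annotation should be applied family-wide.

Reads are assumed to be sense-strand amplicons spanning the VDJ junction.
The reference data convention is a 125-bp read whose final three
nucleotides code the conserved 118Trp (TGG); longer reads work, and a 3'
constant-region overhang can be trimmed (`trim_constant = TRUE`).

## Alignment score and mismatch leniency

Ungapped placements of a germline gene against a read are scored as the
sum of squared lengths of consecutively matched runs minus the sum of
squared lengths of consecutively mismatched runs. Squaring rewards long
exact stretches and punishes clustered disagreement. Point mutations from
hypermutation, however, are mostly isolated, so a leniency rule lets up to
*k* isolated mismatches (runs of length exactly one) be *forgiven*: a
forgiven position contributes zero while its flanking matched runs fuse
into a single squared term. Forgiveness is applied greedily from the 5'
end, where hypermutation is more frequent. Runs of two or more mismatches
are never forgiven, and neither are ambiguous (`N`) positions. A forgiven
mismatch at the very end of a pattern is allowed (it fuses a run with the
boundary, contributing zero); the greedy choice is deliberate and
documented rather than an optimal subset search, and the test suite pins
this semantics against an independent run-fusion oracle over every pattern
of length ≤ 12.

The per-segment leniency budgets: the V segment may forgive up to 15% of
its aligned overlap; the D and J budgets reuse the *observed* V mutation
fraction (`ceiling(fraction × overlap)`), on the logic that a read's
hypermutation load is shared across its segments.

### Placement and boundaries

V is matched first with the last 9 nt of the read withheld, preventing V
from over-running the junction so far that D and J become unresolvable.
Three nucleotides after the V segment are then withheld before J matching,
and everything strictly between V and J is searched for D (minimum
overlaps: 10 nt for V and J, 3 nt for D; these are package choices, kept
configurable). Reverse-complement ("r"-prefixed) D genes are searched by
default. Segment boundaries are taken to the outermost *matching* position
of each aligned overlap: a mismatch run hanging off a segment tip is
junction material (an exonuclease-trimmed germline tail or N insertion),
not segment. Ties between genes are broken by overlap, placement, then
name; when several alleles tie exactly, the whole list is recorded and
pseudogene names are dropped from it if a functional allele ties.

### V indel correction

Single-nucleotide indels 5' of the 104Cys anchor are treated as sequencing
errors and repaired when an insertion or deletion (up to 2 edits) raises
the V score by more than 4 units *and* strictly reduces the mismatch
count. The mismatch condition matters: a genuine indel leaves a
frameshifted, mismatch-rich alignment tail that the repair resolves,
whereas an edit that merely grows the aligned overlap at the read edge
improves the score without fixing anything. The edit search only runs when
the alignment shows a run of ≥ 3 consecutive mismatches before the anchor
(the frameshift signature), which keeps the cost negligible on clean
reads. The CDR3 is never edited, since junction indels can be genuine
recombination products.

## SHM distance and clustering

Reads first group coarsely by CDR3 length and V/J family numbers. Within a
group, pairwise similarity uses the SHM distance: maximal mismatch runs of
length M add M², and every mismatched position adds a weight determined by
the parent→child substitution — −0.5 for the frequently observed C→T,
G→A, A→G, and A→T; 0 for T→C and A→C; +0.5 for the rest. The run-squared
term separates clonally unrelated sequences that share genes but differ in
their N regions; the weights make the distance asymmetric, which is what
allows the direction of descent to be inferred (`shm_distance("ACGCTT",
"ATTGTT")` is 9.5 with the first sequence as parent, 10 the other way, so
the first is called the parent).

Each read links to its nearest neighbour under the symmetrized distance
(ties: higher template count, then id). These links form components with
cyclic dependencies; the root of each component is the cycle member with
the smallest total SHM distance to the other members, ties broken by the
highest total VDJ alignment score, and edges then orient away from the
root. Small trees merge iteratively: a root may become the child of a
sequence in another tree if the distance is within the cutoff (3% of the
compared length by default, user-adjustable); merges apply in ascending
distance order for determinism. Linkage itself is unconditional within the
coarse group up to a sanity bound of 3× the cutoff — without that bound,
two clonally unrelated singletons that merely share a coarse group would
be forcibly chained at distances of 50+ units; with a stricter bound,
genuine parent–child links (typically ~4–6 units at 5 mutations per
generation on 125-bp reads) would be severed. Variable-length members are
compared over their common span right-anchored at the 118Trp codon.

After clustering, every member's gene calls, boundaries, and N-region
demarcations are unified to the root's, a per-cluster germline sequence is
predicted (germline nucleotides over the aligned V/D/J intervals, root
nucleotides over the N regions), and per-member mismatch sets are
recomputed against it. The tree is rerooted if another member lies
strictly closer (raw mismatch count) to the predicted germline; the new
root then recovers its own pre-unification annotation and the cluster
re-unifies, and this cycle repeats (at most three times) until the rooting
is stable. Ties never reroot, so the operation is idempotent.

## TDT model and junction refinement

The probability that an N region was created by TDT rather than uniform
insertion is

P_TDT = Π P_X(j) / (0.25^L + Π P_X(j)),

with per-nucleotide insertion probabilities P_A = 0.25, P_C = 0.08,
P_G = 0.60, P_T = 0.07 (mouse estimates; configurable but not expected to
vary much between healthy subjects). Because TDT may elongate either DNA
strand, the value is the maximum over the sequence and its element-wise
complement — element-wise, *not* reverse-complement, which is what makes
P_TDT("tATC") evaluate to 0.40 via ATAG. The empty region is defined as
the neutral 0.5 so comparisons behave; the region likelihood score is
Nscore = (P_TDT · L)², zero for an empty region.

Two refinement stages run after clustering, in order, at most twice:

**D re-annotation.** A *consensus mismatch* is a position where every
cluster member disagrees with the predicted germline — the signature of a
wrong annotation rather than of hypermutation. If any consensus mismatch
sits in the V framework, the CDR3 ones are presumed by-products of real
mutations and the cluster is left alone. Otherwise, if a CDR3 consensus
mismatch lies in the *interior* of the junction (more than 3 nt from every
segment tip), the D alignment is re-run over all genes and placements, and
an alternative is accepted only if it strictly increases the total of the
V, D, and J alignment scores plus the Nscores of both N regions. The
interior condition is this package's own gate: edge-adjacent consensus
mismatches are demarcation artefacts owned by the edge rules below, and
without the gate the Nscore term — which grows as L² — lets a long,
TDT-plausible stretch of junk outbid a short but correct D gene
(measured on simulated repertoires, ungated refinement *reduced* D
accuracy by ~15 points; gated, it never hurts).

**N-region edge rules.** For each segment edge abutting an N region (V 3',
D 5', D 3', J 5', in that order): (A) a run of ≥ 3 consecutive mismatches
whose near end is within 2 nt of the tip moves into the N region
unconditionally, together with any intervening matching nucleotides (so a
V ending `TG·agg·GG` surrenders `agggg`); (B) where no N region exists,
edge mismatches within 3 nt of the tip — plus everything between them and
the tip — are trimmed into a new N region iff their P_TDT exceeds 0.50
(`gGG` at 0.93 trims; `tATC` at 0.40 does not); (C) where an N region
exists, the candidate extends it iff the combined region's P_TDT strictly
exceeds the candidate's alone (`gGG`+`ccc` = `gggccc` drops 0.93 → 0.31,
so no trim). Trims respect the anchors (the Cys and Trp codons stay in
their segments) and leave at least 1 nt of D. After the edges are
processed the cluster re-unifies.

## Repertoire simulator

The simulator generates truth-annotated repertoires for benchmarking
annotation and SHM identification — deliberately *not* realistic gene
usage: V, D, and J are sampled uniformly so that many combinations get
exercised. Defaults define the benchmark conditions: 1,000 germline
recombination events; per event a 5-generation chain in which each
generation mutates exactly 5 never-before-mutated positions of the lineage
(so generation *g* carries exactly 5·g mutations and the combined output
is 6,000 sequences); 125-nt reads ending on the Trp codon; uniform 0–5 nt
deletions per gene end; uniform 0–8 nt N-region lengths with nucleotides
drawn from the TDT insertion probabilities, complemented with probability
0.5 to model strand choice; and a substitution matrix with the observed
qualitative biases (C→T and G→A dominant; A mutations more frequent than
T mutations; A→G > A→T > A→C). Deletion and N-length ranges are package
choices of realistic magnitude, exposed in `sim_config()`. Only productive
junctions are emitted (in-frame anchors, no junction stop codon);
non-productive draws are rejected and resampled.

What the simulator does *not* model: realistic gene-usage frequencies,
indel-type hypermutation, sequencing error, template-count structure, or
selection. Passing recovery benchmarks on simulated data therefore
demonstrates correct mechanics under idealized mutation, not performance
on real libraries.

## Evaluation metrics

Gene calls are scored as *exact* (full allele-name equality) or
*degenerate* (called allele's sequence ≥ 98% identical to the truth
allele's over the best ungapped overlap of the shorter in the longer —
symmetric by construction). Per-position SHM identification is summarized
as TP/TN/FP/FN with accuracy `(TP+TN)/total` and positive prediction rate
`TP/(TP+FP)` (0 when nothing is called). Substitution propensities count
the 12 ordered X₀→X₁ mutations over *parent–child* pairs from the lineage
trees — not germline–child pairs, which would re-count inherited
mutations — using the parent strand for context, excluding N regions, and
row-normalizing. The V-vs-DJ propensity correlation (Pearson r and the
regression slope of DJ on V) serves as an annotation-quality proxy on real
data, since the mutational machinery does not distinguish segments.
Hot-spot profiles tabulate parent-strand composition at offsets around
mutated positions and, separately, around all positions, so motif
enrichment is judged against the intrinsic positional background. No
multiple-testing correction is applied anywhere: these are descriptive
statistics.

## Numerical and design choices

* Coordinates are 1-based and inclusive throughout.
* Genes without a strain annotation survive strain filtering by default
  (configurable); pseudogenes load and align, but junctions with stops or
  frameshifts are flagged non-productive.
* Reading frame for stop-codon screening comes from the V anchor.
* Duplicate-sequence alleles are retained at load; degeneracy is handled
  at evaluation.
* Reads failing any stage are emitted with a `status` reason
  (`no_v`, `no_j`, `no_d`, `no_cdr3`, `too_short`, `ambiguous_chars`),
  never dropped.
* All randomness flows through R's RNG; fixed seed implies byte-identical
  output.
* Problem sizes in the test suite: the scoring oracle is exhaustive over
  all patterns of length ≤ 12; alignment equivalence is checked on reads
  ≤ 30 nt; end-to-end recovery uses 50 germlines × 5 generations; the
  propensity-correlation property uses 1,000 germlines. These sizes give
  stable statistics at interactive runtimes.

## Known limitations

* **Fragmented deep lineages.** With 5 fresh mutations per generation on a
  125-bp read, the typical parent–child SHM distance (~4.5 units) exceeds
  the default merge cutoff (3% × 125 = 3.75), so nearest-neighbour
  components that split a clonal family often cannot re-merge. Clusters
  remain pure, but a deep family may appear as several trees rooted at
  mid-generation members, which caps how much annotation rescue
  unification can provide and depresses SHM recall in late generations.
  Raising `cutoff_fraction` merges more at the cost of chimera risk.
* **Short D segments are irreducibly ambiguous.** After end deletions a
  true D segment of ≤ 6 nt often matches several database genes equally
  well; no scoring rule can recover the generating gene in that regime.
  With a synthetic database whose genes are mutually ≥ 2 nt distinct,
  degenerate matching coincides with exact matching, so measured
  degenerate D-recovery tracks the harder exact-match statistic.
* VDDJ (double-D) junctions and D-less VJ junctions are out of scope, as
  are light chains and quality-aware alignment.
* The TDT insertion probabilities are fixed mouse estimates; the package
  exposes them but provides no re-estimation from input data.
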