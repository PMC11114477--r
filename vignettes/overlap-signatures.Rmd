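---
title: "Diagnosing small RNA pathways from read-pair overlap signatures"
author: "sncsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing small RNA pathways from read-pair overlap signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncsig)
library(GenomicRanges)
```

## The model

Three classes of animal small RNAs have distinct biogenesis geometries
that survive into an aligned sequencing library:

* **endo-siRNAs**: DICER2 dices long double-stranded RNA into ~21-nt
  duplexes with 2-nt 3′ overhangs.  The plus-strand and minus-strand
  reads of a duplex therefore overlap by `L − 2` nt (19 for `L = 21`).
* **piRNAs**: the ping-pong amplification loop between two PIWI proteins
  produces sense/antisense pairs whose 5′ ends overlap by exactly 10 nt,
  independent of the (24–30 nt) member lengths.
* **miRNAs**: hairpin-derived 20–25 nt reads from the mature and star
  arms of discrete loci; they do not generate an opposite-strand overlap
  signature of their own and are handled by annotation.

Because a library contains abundant unrelated (background) reads, raw
pair counts are uninformative; what identifies a pathway is an *excess*
of pairs at one specific overlap against the distribution over all
overlap groups.  For a read-length stratum `L`, `sncsig` counts weighted
opposite-strand pairs `n_k` per 5′–5′ overlap `k ∈ [4, 20]` and
standardizes within the stratum:

$$z_k = \frac{n_k - \bar n}{\sigma(n)}$$

with mean and *population* standard deviation taken over the 17 overlap
groups.  `z_k > 1` means pairs overlapping by `k` nt are at least one
standard deviation more numerous than the average group.  The Dicer
signature is the call at `k = L − 2` in the `L = 21` stratum; the
ping-pong signature is the call at `k = 10` (for 24–30-nt reads the
mixed-length stratum `"all"` is used after length filtering, because the
two members of a ping-pong pair need not be equally long).

### The overlap convention

All internal coordinates are 1-based closed (the `GRanges` convention).
The 5′ end of a plus-strand read is its `start`; the 5′ end of a
minus-strand read is its `end`.  The 5′–5′ overlap of a (plus, minus)
pair is

```
k = end(minus) − start(plus) + 1
```

which can be zero or negative for disjoint reads.  A pair *counts as
overlapping by k* only when `1 ≤ k ≤ min(length(plus), length(minus))`;
inside that window `k` equals the length of the interval intersection.
This single convention reproduces both anchors: a 21-nt duplex with a
2-nt 3′ overhang gives 19, and a ping-pong pair gives 10.

```{r anchors}
p <- GRanges("chr1", IRanges(101, 121), strand = "+")
m <- GRanges("chr1", IRanges(99, 119), strand = "-")
pairOverlap(p, m)
```

### Pair weighting

The default weighting (`copy_weighted`) scores each pair by the product
of the members' `copies / n_hits`: collapsed copy counts propagate
abundance, and the `1/n_hits` factor splits a multimapper evenly across
its alignments so that reads mapping up to the conventional cap of 100
positions cannot inflate the histogram.  A `raw_pairs` mode (weight 1
per pair) exists for oracle tests and for libraries without copy
annotations.  Whether the original analyses weighted pairs by copy
number is not documented anywhere we could rely on; the default is
therefore a declared assumption, and both modes are exposed.

Population (divisor-`n`) standard deviation is used because the 17
overlap groups are the complete population of groups, not a sample;
it is also stable on tiny fixtures.  A histogram with all groups equal
(for example an empty stratum) has `σ = 0` and is flagged *degenerate*:
all `z_k` are set to 0 and both signatures are called absent, rather
than erroring.

## Pair classification and the discard filters

Candidate pairs are predicted directly from the overlap rules: siRNA
pairs are equal-length pairs (21 nt by default) overlapping by `L − 2`;
piRNA pairs have both lengths in 24–30 nt and overlap exactly 10.  A
candidate is then discarded when, in this order,

1. either member's collapsed copy count ("coverage") is lower than 5;
2. the absolute log2 ratio of the two coverages exceeds 1.5;
3. either member intersects an annotated miRNA locus by ≥ 1 nt.

Only the first failing reason is recorded, which makes the discard
accounting reproducible.  Two points here are interpretations rather
than documented facts and are configurable: the logarithm base (we use
2, the fold-change convention in small-RNA work, compared as an absolute
value) and the meaning of "coverage" (we use the per-read collapsed copy
count, the only per-small-RNA count available before locus calling).

Kept pairs, together with miRNA annotations, drive the class × length
expression profile in RPM (`1e6 × copies / totalMapped`, with
`totalMapped` frozen at read time so RPM stays comparable across
filter settings).  Reads eligible for several classes are assigned by
the precedence miRNA > siRNA > piRNA.  The ovary/soma comparison is a
descriptive pseudocounted log2 fold change per class — deliberately not
a significance test, since replicate-aware differential expression is
out of scope for this package.

## miRNA families

The family module works from a candidate gene table (precursor, mature,
star, read counts) produced upstream by any miRNA predictor, or from the
simulator's truth.  Its rules:

* **Seed** = mature positions 2–8 (7 nt), the MirGeneDB convention; the
  seed is the unit of family identity.
* **Star filter**: novel candidates with star coverage < 5 reads are
  discarded (strict bound: exactly 5 is kept).  Star support validates
  the duplex origin of a predicted locus.
* **Known-family assignment**: the precursor is locally aligned against
  every reference precursor (match +1, mismatch −2, linear gap −3 —
  deliberately simple, score-monotone parameters).  Hits must reach 60%
  identity over at least 50% of the shorter sequence; E-values are not
  used because they depend on database size, which is arbitrary here.
  The best passing hit's family is assigned *only if* the seeds are
  identical; ties break by identity, then lexicographic reference id,
  making assignment order-independent.
* **Novel families**: an undirected graph with edges between genes whose
  precursors align mutually above the same thresholds *and* whose seeds
  differ by at most one substitution; families are connected components
  (single linkage, deterministic ids = smallest member id).  Transitive
  chains can therefore join seeds at distance 2 — documented behaviour,
  because the pairwise rule itself does not specify transitivity.
* **Conservation**: a precursor is "shared" with a second genome when a
  local alignment on either strand reaches 80% identity over 80% of the
  precursor *and* the seed region aligns without a mismatch or indel.
  Requiring seed conservation is an assumption; it matches the use of
  seeds everywhere else in the module.

## Root-to-tip rate comparison

For a rooted newick tree with branch lengths, the root-to-tip distance
of a tip is the sum of branch lengths along its path — a proxy for the
lineage's evolutionary rate.  Two labelled tip groups (e.g. the miRNA
Argonautes against all other Argonautes) are compared with a
Mann–Whitney rank-sum test.  Conventions: `U_A` counts pairs with
`a < b` (ties one half), so `U_A + U_B = n_A n_B`; for
`n_A + n_B ≤ 12` the two-sided p-value is an exact enumeration over all
group labelings (correct under ties); larger samples use the normal
approximation with the standard tie correction.  The choice of test is
itself an assumption — the comparison this mirrors only states
"significantly lower" — so the implementation is configurable to
one-sided alternatives, and trees are used as rooted as written, with
no outgroup logic.

## The simulator

`simulateLibrary()` generates the full study conditions from a single
`SimConfig`:

| parameter | default | meaning |
|---|---|---|
| `genomeLength` | 100 000 b | uniform-random A/C/G/T genome |
| `nMirnaLoci` / `nSirnaLoci` / `nPirnaClusters` | 5 / 3 / 2 | non-overlapping loci, ≥ 50 nt apart |
| `mirnaLocusLen` / `sirnaLocusLen` / `pirnaClusterLen` | 80 / 400 / 2000 nt | locus sizes |
| `nMirnaReads` | 1000 per locus | mature/star reads, ±1 nt end jitter |
| `starFraction` | 0.1 | star-arm probability per read |
| `nSirnaDuplexes` | 500 | 21-nt duplexes, 2-nt overhang |
| `nPirnaPairs` | 500 | ping-pong pairs, lengths 24–30 nt |
| `nBackgroundReads` | 5000 | uniform positions/strands, 18–35 nt |

These defaults are the validation conditions exercised throughout the
test suite (a Dicer library of 500 duplexes over 5000 background reads
on 100 kb, and the analogous ping-pong library); the locus sizes and the
miRNA read depth are our own choices of realistic magnitudes for a
compact test genome.  One master seed drives a single RNG stream in a
fixed draw order — genome, then miRNA loci in order, siRNA loci, piRNA
clusters, background — so identical configurations give byte-identical
FASTA/SAM/FASTQ/TSV outputs.  Copy counts are drawn as `1 + Poisson(4)`
per pair (both duplex members equal, so true pairs have log-ratio 0) and
miRNA/background reads are emitted uncollapsed.  miRNA loci are
rewritten as perfect fold-back hairpins so mature and star arms form a
real duplex; an optional mode duplicates an siRNA locus to create
controlled two-hit multimappers, and an off-by-default flag biases
ping-pong pair positions toward genomic T to mimic the 1U/10A
nucleotide preference (off because the degree of that bias in real
libraries is not something we wish to claim).

What the simulator does **not** emulate: sequencing errors and quality
variation, adapter contamination (trimming is upstream of this
package), transposon-derived sequence composition, phased (Zucchini)
piRNA trails, genuine multimapping from repeat families, or
tissue-dependent composition.  Passing the validation suite therefore
demonstrates correctness of the geometry, weighting and statistics —
not robustness to every artefact of real libraries.

## Numerical and I/O conventions

* Coordinates: 1-based closed internally; BED's 0-based half-open and
  GFF3's 1-based inclusive forms are converted at the boundary by
  rtracklayer.  SAM is written with the read's plus-strand sequence and
  `NH:i:` multiplicity, copies encoded as the `_xN` name suffix.
* Reads failing to parse in a SAM body are an error naming the first
  malformed line, not a silent skip.
* `totalMapped` counts each distinct read once (multimappers are not
  double-counted) and is fixed before filtering.
* Degenerate Z profiles (σ = 0) give all-zero scores, never NaN.
* Rank-sum ties: midranks; exact enumeration includes ties at one half.
* All tie-breaks (best hit, family ids, table orderings) are
  deterministic so reruns are byte-identical.

## Validation scale

The test suite runs entirely on simulated data: signature recovery uses
the default 100 kb / 500-duplex / 5000-background conditions; the null
calibration averages `z_19` over 50 background-only seeds; the
histogram is checked against a brute-force all-pairs oracle on 20
random libraries of up to ~180 reads in both weighting modes; family
recovery uses a 10-family reference; rank-sum enumeration is checked
against the closed-form U on all small splits and against
`stats::wilcox.test` where the latter is exact.

## Known limitations

* The signature operates per read-length stratum; no per-chromosome
  decomposition or positional clustering of the signal is attempted.
* Candidate pair prediction is purely geometric; it does not model
  piRNA phasing, nor does it call genomic piRNA clusters.
* Family assignment depends on reasonably complete reference mature
  annotations; precursors whose mature arm is mis-annotated will fail
  the identical-seed requirement.
* The tissue comparison is descriptive; with biological replicates a
  count-based differential test should be used instead.
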