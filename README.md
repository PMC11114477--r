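# sncsig — read-pair overlap signatures for small RNA pathway diagnosis

Small non-coding RNA classes leave geometric fingerprints in aligned
sequencing libraries.  DICER2 processes long double-stranded RNA into
21-nt endo-siRNA duplexes with 2-nt 3′ overhangs, so the two strands of a
duplex overlap by `L − 2 = 19` nt.  Ping-pong amplified piRNAs (24–30 nt)
come in sense/antisense pairs whose 5′ ends overlap by exactly 10 nt.
When a genome encodes a functional pathway, opposite-strand read pairs
pile up in that overlap group; when it does not, overlaps are spread
evenly.  `sncsig` turns this into a statistic and a set of downstream
classifications, so that presence/absence of the siRNA and piRNA
machinery can be diagnosed directly from a small RNA-seq library — useful
for lineages where the protein repertoire (DICER2, siAGO, PIWI) is
incomplete or unknown.

For every read-length stratum *L* the package counts weighted
opposite-strand pairs *n_k* per 5′–5′ overlap group *k* ∈ [4, 20] and
standardizes them:

```
z_k = (n_k − mean_k(n)) / sd_k(n)        (population sd over the 17 groups)
```

`z_k > 1` means pairs overlapping by *k* nt are at least one standard
deviation more numerous than the average overlap group.  The Dicer
signature is called at `k = L − 2`, the ping-pong signature at `k = 10`.

Around this core the package provides:

* **`simdata`** — a fully seeded simulator (miRNA hairpin loci, siRNA
  duplexes, ping-pong pairs, uniform background; SAM/FASTQ/BED/FASTA
  output with a ground-truth table), so every statistic can be validated
  against known truth.
* **`sncrna_io`** — SAM/BED6 readers (NH multimapper tag, `_xN` collapsed
  copy counts), collapsing, length/multimap filters, RPM normalization.
* **`overlap_signature`** — `pairOverlap()`, `overlapHistogram()`,
  `zscoreProfile()`, `callSignatures()`, `signatureTable()`.
* **`pair_classifier`** — candidate siRNA (overlap `L − 2`) and piRNA
  (overlap 10) pairs with the standard discard filters (member coverage
  < 5, |log2 ratio| > 1.5, miRNA-region overlap) and class × length RPM
  profiles plus a descriptive ovary/soma comparison.
* **`mirna_families`** — star-coverage filter, best-hit family assignment
  requiring an identical 7-nt seed (mature positions 2–8), single-linkage
  clustering of novel families (seed distance ≤ 1), cross-genome
  conservation checks.
* **`tree_metrics`** — root-to-tip distances from newick trees and an
  exact/tie-corrected Mann–Whitney comparison of labelled tip groups.
* **`pipeline_cli`** — `runPipeline()` plus a thin wrapper script
  (`inst/scripts/sncsig.R`) for shell use.

## Worked example

Simulate the default validation library — a 100 kb genome with 5 miRNA
loci (1000 reads each), 500 siRNA duplexes, 500 ping-pong pairs and 5000
background reads — and call the signatures:

```r
library(sncsig)

sim <- simulateLibrary(SimConfig(seed = 42))
sim$library
#> SncLibrary with 12000 alignment(s), 20096 read copies (totalMapped 20,096), tissue: unspecified
#>   read lengths 18-35 nt; 8503 plus / 3497 minus strand

z <- zscoreProfile(overlapHistogram(sim$library, stratumLength = 21))
callSignatures(z, stratumLength = 21)
#>   signature stratum_length overlap_k    z_value present
#> 1     dicer             21        19 3.97874783    TRUE
#> 2  pingpong             21        10 0.05637981   FALSE
```

In the 21-nt stratum the 19-nt overlap group stands almost four standard
deviations above the mean overlap group, so the Dicer signature is
present, while 21-nt reads show no 10-nt ping-pong excess.  The piRNA
signature lives in the 24–30 nt stratum:

```r
pir <- filterReads(sim$library, minLen = 24, maxLen = 30)
round(zscores(zscoreProfile(overlapHistogram(pir, stratumLength = "all"))), 2)
#>     4     5     6     7     8     9    10    11    12    13    14    15    16
#> -0.15 -0.25 -0.37 -0.19 -0.27 -0.24  3.99 -0.23 -0.27 -0.20 -0.37 -0.26 -0.17
#>    17    18    19    20
#> -0.30 -0.32 -0.18 -0.21
```

The sharp peak at `k = 10` is the ping-pong signature of the simulated
piRNA clusters.  `runPipeline()` chains simulation, signature calling,
pair classification and the RPM profiles into one logged, reproducible
run directory.

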