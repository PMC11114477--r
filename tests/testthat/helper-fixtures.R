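# Shared fixtures: all built in code, no files on disk except tempfiles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# One aligned read as a GRanges row.
mk_read <- function(chrom, start, end, strand, id = "r", copies = 1L,
                    n_hits = 1L) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr) <- DataFrame(read_id = id, copies = as.integer(copies),
                         n_hits = as.integer(n_hits))
  gr
}

mk_lib <- function(...) SncLibrary(do.call(c, list(...)))

# Random library over a toy genome; lengths, copies and multiplicities vary.
random_lib <- function(n, seed, glen = 2000L, nchr = 2L) {
  set.seed(seed)
  chrom <- paste0("chr", sample.int(nchr, n, replace = TRUE))
  len <- sample(18:35, n, replace = TRUE)
  start <- sample.int(glen - 40L, n, replace = TRUE)
  gr <- GRanges(chrom, IRanges(start, start + len - 1L),
                strand = sample(c("+", "-"), n, replace = TRUE))
  mcols(gr) <- DataFrame(read_id = paste0("r", seq_len(n)),
                         copies = sample(1:5, n, replace = TRUE),
                         n_hits = sample(1:3, n, replace = TRUE))
  SncLibrary(gr)
}

# Independent O(n^2) oracle for the overlap histogram: enumerate every
# plus/minus pair and apply the 5'-5' geometry arithmetic directly.
brute_hist <- function(lib, stratum, kMin = 4L, kMax = 20L,
                       weighting = "copy_weighted") {
  gr <- reads(lib)
  if (!identical(stratum, "all")) gr <- gr[width(gr) == stratum]
  st <- as.character(strand(gr))
  plus <- gr[st == "+"]; minus <- gr[st == "-"]
  counts <- setNames(numeric(kMax - kMin + 1L), as.character(kMin:kMax))
  for (i in seq_along(plus)) {
    for (j in seq_along(minus)) {
      if (as.character(seqnames(plus))[i] != as.character(seqnames(minus))[j])
        next
      k <- end(minus)[j] - start(plus)[i] + 1L
      if (k < 1L || k < kMin || k > kMax) next
      if (k > min(width(plus)[i], width(minus)[j])) next
      w <- if (weighting == "copy_weighted")
        (mcols(plus)$copies[i] / mcols(plus)$n_hits[i]) *
          (mcols(minus)$copies[j] / mcols(minus)$n_hits[j])
      else 1
      counts[as.character(k)] <- counts[as.character(k)] + w
    }
  }
  counts
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

seed_dist <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])

mutate_dna <- function(seq, positions) {
  s <- strsplit(seq, "")[[1L]]
  for (p in positions) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1L]
  paste(s, collapse = "")
}

# A reference pre-miRNA set of `nfam` one-member families with distinct
# seeds, plus matching candidate genes (identical precursors).
make_family_fixture <- function(nfam = 10L, seed = 101L) {
  set.seed(seed)
  repeat {
    prec <- vapply(seq_len(nfam), function(i) random_dna(70L), character(1))
    mature <- substr(prec, 5L, 26L)
    seeds <- substr(mature, 2L, 8L)
    if (!anyDuplicated(seeds)) break
  }
  ref <- data.frame(id = sprintf("ref-%02d", seq_len(nfam)),
                    family = sprintf("FAM-%02d", seq_len(nfam)),
                    precursor = prec, mature = mature, seed = seeds,
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = sprintf("gene-%02d", seq_len(nfam)),
                      precursor = prec, mature = mature,
                      star = substr(prec, 45L, 66L),
                      mature_count = 100L, star_count = 10L,
                      stringsAsFactors = FALSE)
  list(ref = ref, genes = genes)
}

write_ref_fasta <- function(ref, path) {
  writeLines(as.vector(rbind(
    sprintf(">%s family=%s mature=%s", ref$id, ref$family, ref$mature),
    ref$precursor)), path)
  path
}
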