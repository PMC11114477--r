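test_that("SimConfig validates its geometry", {
  expect_error(SimConfig(genomeLength = 0), "genomeLength")
  expect_error(SimConfig(pirnaLenRange = c(30, 24)), "pirnaLenRange")
  expect_error(SimConfig(sirnaOverhang = 21, sirnaReadLen = 21), "overhang")
  expect_error(SimConfig(starFraction = 1.5), "starFraction")
  expect_s4_class(SimConfig(seed = 3), "SimConfig")
})

test_that("simulateGenome is deterministic and places disjoint gapped loci", {
  cfg <- SimConfig(genomeLength = 100000, nSirnaLoci = 3, nPirnaClusters = 2,
                   nMirnaLoci = 5, seed = 9)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeGenomeAnnotation(g1$genome, g1$loci, dirname(f1), prefix =
                          sub("[.]fa$", "", basename(f1)))
  writeGenomeAnnotation(g2$genome, g2$loci, dirname(f2), prefix =
                          sub("[.]fa$", "", basename(f2)))
  expect_identical(readLines(f1), readLines(f2))

  expect_length(g1$loci, 10L)
  # pairwise gaps of at least 50 nt between loci on the same chromosome
  pad <- GenomicRanges::resize(g1$loci, width(g1$loci) + 100L, fix = "center")
  hits <- GenomicRanges::countOverlaps(pad, g1$loci)
  expect_true(all(hits == 1L))
})

test_that("siRNA duplex geometry gives overlap readLen - overhang for every pair", {
  locus <- GRanges("chr1", IRanges(1001, 1600))
  d <- simulateSirnaDuplexes(locus, 100, readLen = 21, overhang = 2, seed = 5)
  tr <- d$truth
  gr <- d$reads
  for (pid in unique(tr$pair_id)) {
    ids <- tr$read_id[tr$pair_id == pid]
    p <- gr[mcols(gr)$read_id == ids[1L]]
    m <- gr[mcols(gr)$read_id == ids[2L]]
    expect_identical(pairOverlap(p, m), 19L)
  }
  expect_true(all(width(gr) == 21L))

  empty <- simulateSirnaDuplexes(locus, 0)
  expect_length(empty$reads, 0L)
  expect_identical(nrow(empty$truth), 0L)
  expect_error(simulateSirnaDuplexes(locus, -1), "nDuplexes")
  expect_error(simulateSirnaDuplexes(GRanges("chr1", IRanges(1, 20)), 1),
               "too short")
})

test_that("ping-pong pairs all overlap by exactly 10 nt", {
  cl <- GRanges("chr1", IRanges(2001, 4000))
  pp <- simulatePingpongPairs(cl, 200, seed = 6)
  tr <- pp$truth; gr <- pp$reads
  for (pid in unique(tr$pair_id)) {
    ids <- tr$read_id[tr$pair_id == pid]
    p <- gr[mcols(gr)$read_id == ids[1L]]
    m <- gr[mcols(gr)$read_id == ids[2L]]
    expect_identical(pairOverlap(p, m), 10L)
  }
  expect_true(all(width(gr) >= 24L & width(gr) <= 30L))
  expect_length(simulatePingpongPairs(cl, 0)$reads, 0L)
  expect_error(simulatePingpongPairs(cl, 1, lenRange = c(8, 10)), ">= 11")
})

test_that("miRNA reads respect the length window and the star fraction", {
  cfg <- SimConfig(genomeLength = 20000, nMirnaLoci = 1, nSirnaLoci = 0,
                   nPirnaClusters = 0, seed = 10)
  g <- simulateGenome(cfg)
  locus <- g$loci[mcols(g$loci)$class == "mirna"]
  r <- simulateMirnaReads(locus, g$genome, 1000, starFraction = 0.1, seed = 2)
  expect_true(all(width(r$reads) >= 20L & width(r$reads) <= 25L))
  # binomial: 100 +/- 3 * sqrt(1000 * .1 * .9)
  expect_lt(abs(r$gene$star_count - 100), 3 * sqrt(90) + 1e-9)
  expect_identical(r$gene$star_count + r$gene$mature_count, 1000L)
  r0 <- simulateMirnaReads(locus, g$genome, 500, starFraction = 0, seed = 2)
  expect_identical(r0$gene$star_count, 0L)
  # truth record is internally consistent
  expect_true(grepl(r$gene$mature, r$gene$precursor, fixed = TRUE))
  expect_true(grepl(r$gene$star, r$gene$precursor, fixed = TRUE))
  expect_identical(r$gene$seed, substr(r$gene$mature, 2, 8))
})

test_that("background reads are uniform over strands and stay in bounds", {
  sl <- c(chr1 = 60000L, chr2 = 40000L)
  bg <- simulateBackground(sl, 10000, seed = 3)
  gr <- bg$reads
  frac_plus <- mean(as.character(strand(gr)) == "+")
  expect_lt(abs(frac_plus - 0.5), 3 * sqrt(0.25 / 10000))
  expect_true(all(start(gr) >= 1L))
  expect_true(all(end(gr) <= sl[as.character(seqnames(gr))]))
  expect_true(all(width(gr) >= 18L & width(gr) <= 35L))
  expect_length(simulateBackground(sl, 0)$reads, 0L)
  expect_error(simulateBackground(integer(), 5), "non-empty")
})

test_that("simulated read sequences match the genome (revcomp on minus)", {
  sim <- simulateLibrary(SimConfig(genomeLength = 20000, nMirnaLoci = 1,
    nSirnaLoci = 1, nPirnaClusters = 1, nMirnaReads = 20, nSirnaDuplexes = 10,
    nPirnaPairs = 10, nBackgroundReads = 30, seed = 12))
  dir <- tempfile()
  paths <- writeLibrary(sim$library, sim$genome, dir)
  fq <- readLines(paths[["fastq"]])
  ids <- sub("_x[0-9]+$", "", sub("^@", "", fq[seq(1, length(fq), 4)]))
  seqs <- fq[seq(2, length(fq), 4)]
  gr <- reads(sim$library)
  gr <- gr[!duplicated(mcols(gr)$read_id)]
  idx <- match(ids, mcols(gr)$read_id)
  expect_false(anyNA(idx))
  for (i in sample(seq_along(ids), 25)) {
    g <- gr[idx[i]]
    ref <- subseq(sim$genome[[as.character(seqnames(g))]], start(g), end(g))
    if (as.character(strand(g)) == "-") ref <- reverseComplement(ref)
    expect_identical(seqs[i], as.character(ref))
  }
})

test_that("SAM round trip preserves the aligned-read multiset", {
  sim <- simulateLibrary(SimConfig(genomeLength = 20000, nMirnaLoci = 1,
    nSirnaLoci = 1, nPirnaClusters = 1, nMirnaReads = 15, nSirnaDuplexes = 10,
    nPirnaPairs = 10, nBackgroundReads = 50, seed = 4))
  dir <- tempfile()
  paths <- writeLibrary(sim$library, sim$genome, dir, truth = sim$truth)
  lib2 <- readAlignments(paths[["sam"]], "sam")
  keyset <- function(l) {
    g <- reads(l)
    sort(paste(seqnames(g), start(g), end(g), strand(g),
               mcols(g)$copies, mcols(g)$n_hits))
  }
  expect_identical(keyset(lib2), keyset(sim$library))
  expect_identical(totalMapped(lib2), totalMapped(sim$library))
  # truth row count = distinct read ids
  tr <- read.delim(paths[["truth"]])
  expect_identical(nrow(tr), length(unique(tr$read_id)))
  expect_identical(sort(unique(tr$read_id)),
                   sort(unique(mcols(reads(sim$library))$read_id)))
})

test_that("an empty library writes a valid headers-only SAM", {
  genome <- DNAStringSet(c(chr1 = random_dna(500, seed = 1)))
  lib <- SncLibrary()
  dir <- tempfile()
  paths <- writeLibrary(lib, genome, dir)
  sam <- readLines(paths[["sam"]])
  expect_true(all(grepl("^@", sam)))
  expect_length(reads(readAlignments(paths[["sam"]], "sam")), 0L)
})

test_that("multimapper mode emits duplicated alignments with n_hits = 2", {
  sim <- simulateLibrary(SimConfig(genomeLength = 30000, nMirnaLoci = 0,
    nPirnaClusters = 0, nSirnaLoci = 1, nSirnaDuplexes = 20,
    nBackgroundReads = 0, multimapDuplicate = TRUE, seed = 8))
  gr <- reads(sim$library)
  expect_true(all(mcols(gr)$n_hits == 2L))
  tab <- table(mcols(gr)$read_id)
  expect_true(all(tab == 2L))
  # depth counts each read once despite two alignments
  expect_identical(totalMapped(sim$library),
                   sum(as.numeric(mcols(gr)$copies)) / 2)
})
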