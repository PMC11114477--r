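test_that("candidate pairs follow the overlap rules of each class", {
  dup <- mk_lib(mk_read("chr1", 101, 121, "+", "p", copies = 8L),
                mk_read("chr1", 99, 119, "-", "m", copies = 8L))
  si <- findCandidatePairs(dup, "sirna")
  expect_identical(nrow(si), 1L)
  expect_identical(si$overlap, 19L)
  expect_identical(si$log_ratio, 0)

  pp <- mk_lib(mk_read("chr1", 101, 128, "+", "p", copies = 6L),
               mk_read("chr1", 85, 110, "-", "m", copies = 6L))
  pi <- findCandidatePairs(pp, "pirna")
  expect_identical(nrow(pi), 1L)
  expect_identical(pi$overlap, 10L)

  # a 21-nt pair overlapping by 12 is no candidate for either class
  off <- mk_lib(mk_read("chr1", 101, 121, "+", "p"),
                mk_read("chr1", 92, 112, "-", "m"))
  expect_identical(nrow(findCandidatePairs(off, "sirna")), 0L)
  expect_identical(nrow(findCandidatePairs(off, "pirna")), 0L)
  expect_error(findCandidatePairs(dup, "mirna"), "arg")
})

test_that("filters are applied in order with a single recorded reason", {
  mk_pair <- function(covp, covm, start = 101L) {
    lib <- mk_lib(mk_read("chr1", start, start + 20L, "+", paste0("p", start),
                          copies = covp),
                  mk_read("chr1", start - 2L, start + 18L, "-",
                          paste0("m", start), copies = covm))
    findCandidatePairs(lib, "sirna")
  }
  pairs <- rbind(mk_pair(4L, 10L, 101L),    # low coverage
                 mk_pair(40L, 10L, 201L),   # log2(4) = 2 > 1.5
                 mk_pair(8L, 8L, 301L),     # kept
                 mk_pair(3L, 40L, 401L),    # fails both -> low_coverage wins
                 mk_pair(9L, 9L, 501L))     # in miRNA region (below)
  regions <- GRanges("chr1", IRanges(505, 560))
  flt <- filterPairs(pairs, minCoverage = 5, maxAbsLogRatio = 1.5,
                     mirnaRegions = regions)
  expect_identical(flt$discard_reason,
                   c("low_coverage", "log_ratio", "none", "low_coverage",
                     "mirna_region"))
  expect_identical(flt$status == "kept", flt$discard_reason == "none")
  # partition: every input row present with exactly one reason
  expect_identical(nrow(flt), nrow(pairs))
  expect_error(filterPairs(pairs, minCoverage = 0), "minCoverage")
})

test_that("filtering is monotone in coverage threshold and regions", {
  sim <- simulateLibrary(SimConfig(genomeLength = 30000, nMirnaLoci = 0,
    nPirnaClusters = 1, nSirnaLoci = 1, nSirnaDuplexes = 60, nPirnaPairs = 60,
    nBackgroundReads = 300, seed = 17))
  lib <- collapseReads(sim$library)
  cand <- rbind(findCandidatePairs(lib, "sirna"),
                findCandidatePairs(lib, "pirna"))
  kept_n <- vapply(c(1L, 3L, 5L, 8L), function(mc)
    sum(filterPairs(cand, minCoverage = mc)$status == "kept"), integer(1))
  expect_true(all(diff(kept_n) <= 0L))
  small <- GRanges("chr1", IRanges(1, 500))
  wide <- GRanges("chr1", IRanges(1, 30000))
  expect_gte(sum(filterPairs(cand, mirnaRegions = small)$status == "kept"),
             sum(filterPairs(cand, mirnaRegions = wide)$status == "kept"))
})

test_that("swapping member coverages negates the log ratio", {
  a <- mk_lib(mk_read("chr1", 101, 121, "+", "p", copies = 12L),
              mk_read("chr1", 99, 119, "-", "m", copies = 3L))
  b <- mk_lib(mk_read("chr1", 101, 121, "+", "p", copies = 3L),
              mk_read("chr1", 99, 119, "-", "m", copies = 12L))
  ra <- findCandidatePairs(a, "sirna")$log_ratio
  rb <- findCandidatePairs(b, "sirna")$log_ratio
  expect_identical(ra, -rb)
  fa <- filterPairs(findCandidatePairs(a, "sirna"), minCoverage = 1)
  fb <- filterPairs(findCandidatePairs(b, "sirna"), minCoverage = 1)
  expect_identical(fa$status, fb$status)
})

test_that("all truth pairs are recovered at permissive settings", {
  sim <- simulateLibrary(SimConfig(genomeLength = 40000, nMirnaLoci = 0,
    nPirnaClusters = 1, nSirnaLoci = 1, nSirnaDuplexes = 50, nPirnaPairs = 50,
    nBackgroundReads = 200, seed = 19))
  lib <- collapseReads(sim$library)
  kept <- rbind(
    filterPairs(findCandidatePairs(lib, "sirna"), minCoverage = 1,
                maxAbsLogRatio = Inf),
    filterPairs(findCandidatePairs(lib, "pirna"), minCoverage = 1,
                maxAbsLogRatio = Inf))
  kept <- kept[kept$status == "kept", ]
  gr <- reads(sim$library)
  tr <- sim$truth[sim$truth$class %in% c("sirna", "pirna"), ]
  for (pid in unique(tr$pair_id)) {
    ids <- tr$read_id[tr$pair_id == pid]
    cls <- tr$class[tr$pair_id == pid][1L]
    p <- gr[mcols(gr)$read_id == ids[1L]]
    m <- gr[mcols(gr)$read_id == ids[2L]]
    hit <- kept$class == cls &
      kept$plus_start == start(p) & kept$plus_end == end(p) &
      kept$minus_start == start(m) & kept$minus_end == end(m)
    expect_true(any(hit))
  }
})

test_that("class profiles sum RPM per class and length", {
  # toy 3-class library with hand-computable RPM
  lib <- mk_lib(
    mk_read("chr1", 101, 121, "+", "sp", copies = 10L),   # sirna pair
    mk_read("chr1", 99, 119, "-", "sm", copies = 10L),
    mk_read("chr1", 501, 528, "+", "pp", copies = 20L),   # pirna pair (28/26)
    mk_read("chr1", 485, 510, "-", "pm", copies = 20L),
    mk_read("chr1", 901, 922, "+", "mi", copies = 40L))   # mirna region read
  # totalMapped = 100 -> rpm = copies * 1e4
  kept <- rbind(filterPairs(findCandidatePairs(lib, "sirna"), minCoverage = 1),
                filterPairs(findCandidatePairs(lib, "pirna"), minCoverage = 1))
  ann <- GRanges("chr1", IRanges(880, 960))
  prof <- classLengthProfile(lib, kept, ann)
  get <- function(cl, len) prof$rpm[prof$class == cl & prof$length == len]
  expect_equal(get("mirna", 22), 40 * 1e4)
  expect_equal(get("sirna", 21), 2 * 10 * 1e4)
  expect_equal(get("pirna", 28), 20 * 1e4)
  expect_equal(get("pirna", 26), 20 * 1e4)
  expect_true(all(prof$length[prof$class == "pirna"] %in% 24:30))
  # empty library -> empty profile
  expect_identical(nrow(classLengthProfile(SncLibrary(totalMapped = 1))), 0L)
})

test_that("miRNA precedence wins over pair classes with a message", {
  lib <- mk_lib(mk_read("chr1", 101, 121, "+", "p", copies = 10L),
                mk_read("chr1", 99, 119, "-", "m", copies = 10L))
  kept <- filterPairs(findCandidatePairs(lib, "sirna"), minCoverage = 1)
  ann <- GRanges("chr1", IRanges(90, 130))
  expect_message(prof <- classLengthProfile(lib, kept, ann), "precedence")
  expect_identical(unique(prof$class), "mirna")
})

test_that("tissue comparison uses pseudocounted log2 fold changes", {
  po <- data.frame(class = c("mirna", "pirna"), length = c(22L, 28L),
                   rpm = c(100, 999))
  ps <- data.frame(class = c("mirna", "pirna"), length = c(22L, 28L),
                   rpm = c(100, 99))
  fc <- compareTissues(po, ps)
  expect_equal(fc$log2_fc[fc$class == "mirna"], 0)
  expect_equal(fc$log2_fc[fc$class == "pirna"], log2(1000 / 100))
  # class absent from one tissue stays finite
  fc2 <- compareTissues(po, ps[ps$class == "mirna", ])
  expect_true(is.finite(fc2$log2_fc[fc2$class == "pirna"]))
  fc3 <- compareTissues(po, po)
  expect_true(all(fc3$log2_fc == 0))
})
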