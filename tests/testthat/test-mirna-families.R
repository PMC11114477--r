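test_that("seed extraction takes mature positions 2-8 with U/T normalization", {
  expect_identical(extractSeed("TGAGGTAGTAGGTTGTATAGTT"), "GAGGTAG")
  expect_identical(extractSeed("ugagguaguagguuguauaguu"), "GAGGTAG")
  expect_identical(extractSeed("ACGTACGT"), "CGTACGT")   # 8-nt boundary
  expect_error(extractSeed("ACGTACG"), "at least 8")
})

test_that("star filter discards below-5 star support, strictly", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      star_count = c(4L, 5L, 0L, 100L))
  kept <- starFilter(genes)
  expect_identical(kept$gene_id, c("b", "d"))
  expect_identical(starFilter(genes, minStar = 0L)$gene_id, genes$gene_id)
  # monotone in the threshold
  sizes <- vapply(0:6, function(m) nrow(starFilter(genes, m)), integer(1))
  expect_true(all(diff(sizes) <= 0L))
  # known-family genes are never removed
  genes$family <- c("FAM-1", NA, NA, NA)
  expect_true("a" %in% starFilter(genes, 5L)$gene_id)
  expect_error(starFilter(genes, -1L), "minStar")
})

test_that("known-family assignment needs a passing best hit AND identical seed", {
  fx <- make_family_fixture(nfam = 6L, seed = 55L)
  asg <- assignKnownFamily(validateMirnaGenes(fx$genes), fx$ref)
  expect_identical(asg$family, fx$ref$family)   # self-hits, identical seeds
  expect_true(all(!asg$novel))

  # same best hit but one seed mismatch -> unassigned
  g2 <- fx$genes[1L, ]
  seed_pos <- 6L   # inside mature positions 2..8 (precursor offset 4 + pos)
  g2$precursor <- mutate_dna(g2$precursor, 4L + seed_pos)
  g2$mature <- substr(g2$precursor, 5L, 26L)
  asg2 <- assignKnownFamily(validateMirnaGenes(g2), fx$ref)
  expect_identical(asg2$best_hit, fx$ref$id[1L])
  expect_true(is.na(asg2$family))
  expect_true(asg2$novel)

  # no reference passes the thresholds -> unassigned
  stranger <- data.frame(gene_id = "x", precursor = random_dna(70, seed = 77),
                         mature = NA, star = NA, mature_count = 1L,
                         star_count = 10L)
  stranger$mature <- substr(stranger$precursor, 5L, 26L)
  stranger$star <- substr(stranger$precursor, 45L, 66L)
  asg3 <- assignKnownFamily(validateMirnaGenes(stranger), fx$ref)
  expect_true(is.na(asg3$family))
  # empty reference -> everything novel, no error
  asg4 <- assignKnownFamily(validateMirnaGenes(fx$genes), fx$ref[0L, ])
  expect_true(all(asg4$novel))
})

test_that("assignment is invariant to reference row order", {
  fx <- make_family_fixture(nfam = 5L, seed = 60L)
  genes <- validateMirnaGenes(fx$genes)
  a1 <- assignKnownFamily(genes, fx$ref)
  set.seed(1)
  a2 <- assignKnownFamily(genes, fx$ref[sample.int(nrow(fx$ref)), ])
  expect_identical(a1$family, a2$family)
  expect_identical(a1$best_hit, a2$best_hit)
})

test_that("novel families are single-linkage components over mutual hits", {
  base <- random_dna(70, seed = 91)
  seed_cols <- 6:12   # precursor columns of mature positions 2..8
  gA <- base
  gB <- mutate_dna(base, c(seed_cols[2L], 40L))       # seed dist 1 from A
  gC <- mutate_dna(gB, c(seed_cols[5L], 55L))         # dist 1 from B, 2 from A
  other <- random_dna(70, seed = 92)
  # make the second cluster's seed far from the first
  gD <- other
  gE <- mutate_dna(other, 62L)                        # same seed as D
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    precursor = c(gA, gB, gC, gD, gE), stringsAsFactors = FALSE)
  genes$mature <- substr(genes$precursor, 5L, 26L)
  genes$star <- substr(genes$precursor, 45L, 66L)
  genes$mature_count <- 10L; genes$star_count <- 10L
  genes <- validateMirnaGenes(genes)
  expect_gte(seed_dist(genes$seed[1L], genes$seed[4L]), 2L)
  fam <- clusterNovelFamilies(genes)
  split_fam <- split(fam$gene_id, fam$family_id)
  expect_identical(unname(sort(vapply(split_fam, paste, character(1),
                                      collapse = ","))),
                   sort(c("gA,gB,gC", "gD,gE")))
  # family id = lexicographically smallest member
  expect_true(all(mapply(function(id, members) id == min(members),
                         names(split_fam), split_fam)))
  # invariant to input order
  set.seed(2)
  fam2 <- clusterNovelFamilies(genes[sample.int(nrow(genes)), ])
  expect_identical(fam, fam2)
  # two dissimilar seeds stay apart even with similar precursors
  gF <- mutate_dna(base, seed_cols[c(1L, 3L)])        # seed dist 2 from A
  g2 <- genes[1L, ]; g2 <- rbind(g2, g2)
  g2$gene_id <- c("gA", "gF"); g2$precursor <- c(gA, gF)
  g2$mature <- substr(g2$precursor, 5L, 26L)
  g2$star <- substr(g2$precursor, 45L, 66L)
  fam3 <- clusterNovelFamilies(validateMirnaGenes(g2))
  expect_identical(length(unique(fam3$family_id)), 2L)
})

test_that("conservation requires high identity, coverage and an intact seed", {
  prec <- random_dna(60, seed = 120)
  gene <- data.frame(gene_id = "g1", precursor = prec,
                     mature = substr(prec, 5L, 26L),
                     star = substr(prec, 40L, 58L),
                     mature_count = 50L, star_count = 8L)
  gene <- validateMirnaGenes(gene)
  flank <- random_dna(400, seed = 121)
  planted <- Biostrings::DNAStringSet(c(s1 = paste0(flank, prec,
                                                    random_dna(400, seed = 122))))
  hit <- conservationCheck(gene, planted)
  expect_true(hit$shared)
  expect_identical(attr(hit, "n_shared"), 1L)
  # reverse-complement planting is also found
  rc <- Biostrings::reverseComplement(planted)
  expect_true(conservationCheck(gene, rc)$shared)
  # absent from a random genome
  rand <- Biostrings::DNAStringSet(c(s1 = random_dna(1000, seed = 123)))
  expect_false(conservationCheck(gene, rand)$shared)
  # ~70% identity misses the default 0.8 threshold
  degraded <- mutate_dna(prec, seq(2L, 59L, by = 3L))  # ~1/3 of positions
  dg <- Biostrings::DNAStringSet(c(s1 = paste0(flank, degraded,
                                               random_dna(400, seed = 124))))
  expect_false(conservationCheck(gene, dg)$shared)
  # a seed mutation alone breaks conservation
  seed_broken <- mutate_dna(prec, 7L)   # inside mature positions 2..8
  sb <- Biostrings::DNAStringSet(c(s1 = paste0(flank, seed_broken,
                                               random_dna(400, seed = 125))))
  expect_false(conservationCheck(gene, sb)$shared)
  expect_error(conservationCheck(gene, Biostrings::DNAStringSet()),
               "non-empty")
})

test_that("simulated miRNA genes are re-assigned to their source families", {
  sim <- simulateLibrary(SimConfig(genomeLength = 40000, nMirnaLoci = 4,
    nSirnaLoci = 0, nPirnaClusters = 0, nMirnaReads = 50,
    nBackgroundReads = 0, seed = 31))
  genes <- validateMirnaGenes(sim$genes)
  ref <- data.frame(id = paste0("ref_", genes$gene_id),
                    family = paste0("FAM_", genes$gene_id),
                    precursor = genes$precursor, mature = genes$mature,
                    seed = genes$seed, stringsAsFactors = FALSE)
  asg <- assignKnownFamily(genes, ref)
  expect_identical(asg$family, paste0("FAM_", genes$gene_id))
})
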