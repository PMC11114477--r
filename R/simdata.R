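#' Simulate a genome with annotated small-RNA loci
#'
#' Draws a uniform-random A/C/G/T genome of `genomeLength(config)` bases
#' split over `nChromosomes` chromosomes, then places non-overlapping loci
#' (miRNA hairpins, dsRNA/siRNA loci, piRNA clusters) separated by at least
#' 50 nt.  miRNA loci are rewritten as fold-back hairpins: the 3' arm is the
#' reverse complement of the 5' arm, so mature and star reads form a proper
#' duplex.  With `multimapDuplicate = TRUE` the first siRNA locus sequence
#' is copied verbatim to an extra locus (class `sirna_copy`) to create
#' controlled two-hit multimappers.
#'
#' @param config a [SimConfig-class].
#' @param seed integer PRNG seed; defaults to `config@seed`.  Pass `NULL`
#'   to consume the current RNG stream (used by [simulateLibrary()]).
#' @return A list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `loci` (`GRanges` with mcols `locus_id`, `class`).
#' @examples
#' sim <- simulateGenome(SimConfig(genomeLength = 20000, nMirnaLoci = 2,
#'                                 nSirnaLoci = 1, nPirnaClusters = 1))
#' sim$loci
#' @export
simulateGenome <- function(config, seed = config@seed) {
  validObject(config)
  .maybe_seed(seed)
  nchr <- config@nChromosomes
  base_len <- config@genomeLength %/% nchr
  lens <- rep(base_len, nchr)
  lens[nchr] <- lens[nchr] + config@genomeLength %% nchr
  if (any(lens <= 0L)) stop("genomeLength too small for ", nchr, " chromosomes")
  names(lens) <- paste0("chr", seq_len(nchr))
  genome <- Biostrings::DNAStringSet(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))

  n_copy <- if (config@multimapDuplicate && config@nSirnaLoci > 0L) 1L else 0L
  classes <- rep(c("mirna", "sirna", "pirna", "sirna_copy"),
                 c(config@nMirnaLoci, config@nSirnaLoci,
                   config@nPirnaClusters, n_copy))
  widths <- rep(c(config@mirnaLocusLen, config@sirnaLocusLen,
                  config@pirnaClusterLen, config@sirnaLocusLen),
                c(config@nMirnaLoci, config@nSirnaLoci,
                  config@nPirnaClusters, n_copy))
  loci <- .place_loci(lens, classes, widths, gap = 50L)

  # carve hairpins into the miRNA loci: 3' arm := revcomp(5' arm)
  is_mir <- which(S4Vectors::mcols(loci)$class == "mirna")
  for (i in is_mir) {
    ch <- as.character(GenomeInfoDb::seqnames(loci)[i])
    s <- BiocGenerics::start(loci)[i]; e <- BiocGenerics::end(loci)[i]
    L <- e - s + 1L
    arm <- L %/% 3L
    arm5 <- Biostrings::subseq(genome[[ch]], s, s + arm - 1L)
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]], IRanges::IRanges(e - arm + 1L, e),
      Biostrings::reverseComplement(arm5))
  }

  # verbatim copy of the first siRNA locus for the multimapper mode
  if (n_copy) {
    mc <- S4Vectors::mcols(loci)
    src <- which(mc$class == "sirna")[1L]
    dst <- which(mc$class == "sirna_copy")[1L]
    src_seq <- Biostrings::subseq(
      genome[[as.character(GenomeInfoDb::seqnames(loci)[src])]],
      BiocGenerics::start(loci)[src], BiocGenerics::end(loci)[src])
    dch <- as.character(GenomeInfoDb::seqnames(loci)[dst])
    genome[[dch]] <- Biostrings::replaceAt(
      genome[[dch]],
      IRanges::IRanges(BiocGenerics::start(loci)[dst], BiocGenerics::end(loci)[dst]),
      src_seq)
  }
  list(genome = genome, loci = loci)
}

# Rejection-sample non-overlapping loci with >= `gap` nt between them.
.place_loci <- function(seqlens, classes, widths, gap = 50L) {
  if (!length(classes)) {
    loci <- GenomicRanges::GRanges(seqlengths = seqlens)
    S4Vectors::mcols(loci) <- S4Vectors::DataFrame(locus_id = character(),
                                                   class = character())
    return(loci)
  }
  placed <- GenomicRanges::GRanges(seqlengths = seqlens)
  out <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    w <- widths[i]
    ok_chr <- names(seqlens)[seqlens >= w]
    if (!length(ok_chr))
      stop("cannot place a ", classes[i], " locus of ", w,
           " nt: no chromosome is long enough")
    hit <- NULL
    for (try in seq_len(1000L)) {
      ch <- if (length(ok_chr) == 1L) ok_chr else
        sample(ok_chr, 1L, prob = seqlens[ok_chr])
      s <- sample.int(seqlens[[ch]] - w + 1L, 1L)
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + w - 1L),
                                     seqlengths = seqlens)
      pad <- GenomicRanges::resize(cand, w + 2L * gap, fix = "center")
      pad <- GenomicRanges::trim(pad)
      if (!length(placed) ||
          sum(GenomicRanges::countOverlaps(pad, placed)) == 0L) {
        hit <- cand
        break
      }
    }
    if (is.null(hit))
      stop("could not place ", classes[i],
           " locus without overlap after 1000 attempts; ",
           "reduce locus counts or enlarge the genome")
    placed <- c(placed, hit)
    out[[i]] <- hit
  }
  loci <- do.call(c, out)
  idx <- stats::ave(seq_along(classes), classes, FUN = seq_along)
  S4Vectors::mcols(loci)$locus_id <- paste0(classes, "_", idx)
  S4Vectors::mcols(loci)$class <- classes
  loci
}

.empty_truth <- function() {
  data.frame(read_id = character(), class = character(),
             locus_id = character(), pair_id = character(),
             stringsAsFactors = FALSE)
}

.reads_gr <- function(chrom, start, end, strand, read_id, copies, seqlens) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, seqlengths = seqlens)
  S4Vectors::mcols(gr)$read_id <- read_id
  S4Vectors::mcols(gr)$copies <- as.integer(copies)
  S4Vectors::mcols(gr)$n_hits <- rep(1L, length(gr))
  gr
}

#' Simulate DICER2 siRNA duplexes from a dsRNA locus
#'
#' Each duplex is a plus-strand read of `readLen` nt starting at a position
#' `x` inside the locus, paired with a minus-strand read of the same length
#' whose interval is shifted upstream by the 3' overhang.  The 5'-5'
#' overlap of the pair is therefore exactly `readLen - overhang` nt (19 for
#' the canonical 21-nt duplex with a 2-nt overhang).  Start positions are
#' uniform within the locus, or tiled every `readLen` nt when
#' `phased = TRUE`.  Both members of a duplex get the same collapsed copy
#' count, drawn as `1 + Poisson(4)`.
#'
#' @param locus a length-1 `GRanges` for the dsRNA locus.
#' @param nDuplexes number of duplexes to emit.
#' @param readLen siRNA read length in nt (default 21).
#' @param overhang 3' overhang in nt (default 2).
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @param phased tile duplex starts instead of sampling them.
#' @return A list with `reads` (`GRanges`, mcols `read_id`, `copies`,
#'   `n_hits`) and `truth` (data.frame `read_id`, `class`, `locus_id`,
#'   `pair_id`).
#' @examples
#' locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
#' dup <- simulateSirnaDuplexes(locus, nDuplexes = 3, seed = 1)
#' pairOverlap(dup$reads[1], dup$reads[2])   # 19
#' @export
simulateSirnaDuplexes <- function(locus, nDuplexes, readLen = 21L,
                                  overhang = 2L, seed = NULL, phased = FALSE) {
  stopifnot(is(locus, "GRanges"), length(locus) == 1L)
  nDuplexes <- as.integer(nDuplexes)
  if (is.na(nDuplexes) || nDuplexes < 0L) stop("nDuplexes must be >= 0")
  readLen <- as.integer(readLen); overhang <- as.integer(overhang)
  if (overhang < 0L || overhang >= readLen)
    stop("overhang must satisfy 0 <= overhang < readLen")
  if (BiocGenerics::width(locus) < readLen + overhang)
    stop("locus too short for a ", readLen, "-nt duplex with ", overhang,
         "-nt overhang")
  .maybe_seed(seed)
  if (nDuplexes == 0L)
    return(list(reads = .reads_gr(character(), integer(), integer(),
                                  character(), character(), integer(),
                                  GenomeInfoDb::seqlengths(locus)),
                truth = .empty_truth()))
  lo <- BiocGenerics::start(locus) + overhang
  hi <- BiocGenerics::end(locus) - readLen + 1L
  x <- if (phased) {
    lo + ((seq_len(nDuplexes) - 1L) * readLen) %% (hi - lo + 1L)
  } else {
    lo + sample.int(hi - lo + 1L, nDuplexes, replace = TRUE) - 1L
  }
  cov <- 1L + stats::rpois(nDuplexes, 4)
  lid <- S4Vectors::mcols(locus)$locus_id
  if (is.null(lid)) lid <- "sirna_locus"
  pair_id <- paste0(lid, "_dup", seq_len(nDuplexes))
  chrom <- as.character(GenomeInfoDb::seqnames(locus))
  plus <- .reads_gr(chrom, x, x + readLen - 1L, "+",
                    paste0(pair_id, "_p"), cov,
                    GenomeInfoDb::seqlengths(locus))
  minus <- .reads_gr(chrom, x - overhang, x - overhang + readLen - 1L, "-",
                     paste0(pair_id, "_m"), cov,
                     GenomeInfoDb::seqlengths(locus))
  reads <- c(plus, minus)
  truth <- data.frame(
    read_id = c(paste0(pair_id, "_p"), paste0(pair_id, "_m")),
    class = "sirna", locus_id = lid,
    pair_id = rep(pair_id, 2L), stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate ping-pong piRNA pairs from a piRNA cluster
#'
#' A ping-pong pair is a plus-strand read whose 5' end sits at position `x`
#' and a minus-strand read whose 5' end sits at `x + 9`, so the two 5' ends
#' overlap by exactly 10 nt regardless of the member lengths, which are
#' drawn independently and uniformly from `lenRange` (24-30 nt by default).
#' With `fivePrimeBias = TRUE` (requires `genome`) pair positions are
#' preferentially drawn where the genome carries a T, emulating the 1U/10A
#' nucleotide bias of ping-pong piRNAs; the flag is off by default.
#'
#' @param cluster a length-1 `GRanges` for the piRNA cluster.
#' @param nPairs number of pairs to emit.
#' @param lenRange integer(2) piRNA length range; `max(lenRange)` must be
#'   at least 11 so the 10-nt overlap is shorter than both members.
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @param memberLengths optional integer(2) `(plus, minus)` fixed lengths,
#'   overriding the random draw (useful for worked examples).
#' @param fivePrimeBias logical, see Description.
#' @param genome `DNAStringSet`, required when `fivePrimeBias = TRUE`.
#' @return A list with `reads` and `truth` as in [simulateSirnaDuplexes()].
#' @examples
#' cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 4000))
#' pp <- simulatePingpongPairs(cl, 1, memberLengths = c(28, 26), seed = 1)
#' pairOverlap(pp$reads[1], pp$reads[2])   # 10
#' @export
simulatePingpongPairs <- function(cluster, nPairs, lenRange = c(24L, 30L),
                                  seed = NULL, memberLengths = NULL,
                                  fivePrimeBias = FALSE, genome = NULL) {
  stopifnot(is(cluster, "GRanges"), length(cluster) == 1L)
  nPairs <- as.integer(nPairs)
  if (is.na(nPairs) || nPairs < 0L) stop("nPairs must be >= 0")
  lenRange <- as.integer(lenRange)
  if (length(lenRange) != 2L || lenRange[1L] > lenRange[2L] || any(lenRange < 1L))
    stop("lenRange must be a positive interval with min <= max")
  if (lenRange[2L] < 11L)
    stop("lenRange max must be >= 11: a 10-nt 5' overlap cannot fit ",
         "strictly inside shorter reads")
  maxLen <- if (is.null(memberLengths)) lenRange[2L] else max(memberLengths)
  if (BiocGenerics::width(cluster) < maxLen + 10L)
    stop("cluster too short for ping-pong pairs of up to ", maxLen, " nt")
  .maybe_seed(seed)
  if (nPairs == 0L)
    return(list(reads = .reads_gr(character(), integer(), integer(),
                                  character(), character(), integer(),
                                  GenomeInfoDb::seqlengths(cluster)),
                truth = .empty_truth()))
  if (!is.null(memberLengths)) {
    memberLengths <- as.integer(memberLengths)
    stopifnot(length(memberLengths) == 2L)
    lp <- rep(memberLengths[1L], nPairs)
    lm <- rep(memberLengths[2L], nPairs)
  } else {
    lp <- sample(seq.int(lenRange[1L], lenRange[2L]), nPairs, replace = TRUE)
    lm <- sample(seq.int(lenRange[1L], lenRange[2L]), nPairs, replace = TRUE)
  }
  # plus 5' end x; minus 5' end x + 9; keep both members inside the cluster
  lo <- BiocGenerics::start(cluster) + max(0L, max(lm) - 10L)
  hi <- BiocGenerics::end(cluster) - max(max(lp) - 1L, 9L)
  if (hi < lo) stop("cluster too short for the requested member lengths")
  pool <- seq.int(lo, hi)
  if (fivePrimeBias) {
    if (is.null(genome)) stop("fivePrimeBias requires the genome")
    ch <- genome[[as.character(GenomeInfoDb::seqnames(cluster))]]
    lett <- strsplit(as.character(Biostrings::subseq(ch, lo, hi)), "")[[1L]]
    tpos <- pool[lett == "T"]
    if (length(tpos)) pool <- tpos
  }
  x <- pool[sample.int(length(pool), nPairs, replace = TRUE)]
  cov <- 1L + stats::rpois(nPairs, 4)
  lid <- S4Vectors::mcols(cluster)$locus_id
  if (is.null(lid)) lid <- "pirna_cluster"
  pair_id <- paste0(lid, "_pp", seq_len(nPairs))
  chrom <- as.character(GenomeInfoDb::seqnames(cluster))
  plus <- .reads_gr(chrom, x, x + lp - 1L, "+", paste0(pair_id, "_p"), cov,
                    GenomeInfoDb::seqlengths(cluster))
  minus <- .reads_gr(chrom, x + 10L - lm, x + 9L, "-", paste0(pair_id, "_m"),
                     cov, GenomeInfoDb::seqlengths(cluster))
  truth <- data.frame(
    read_id = c(paste0(pair_id, "_p"), paste0(pair_id, "_m")),
    class = "pirna", locus_id = lid,
    pair_id = rep(pair_id, 2L), stringsAsFactors = FALSE)
  list(reads = c(plus, minus), truth = truth)
}

#' Simulate mature/star reads from a miRNA hairpin locus
#'
#' The locus is interpreted as a hairpin whose 5' arm hosts the canonical
#' mature miRNA (22 nt, clamped into `matureLenRange`) and whose 3' arm
#' hosts the star (passenger) strand.  Reads are drawn from the mature arm
#' with probability `1 - starFraction` and from the star arm otherwise,
#' with independent uniform jitter of -1/0/+1 nt at both the 5' and 3'
#' ends, truncated so every emitted length stays inside `matureLenRange`.
#' Both arms are read on the precursor (plus) strand.
#'
#' @param locus length-1 `GRanges` of the hairpin (as placed by
#'   [simulateGenome()]).
#' @param genome the simulated genome (`DNAStringSet`); used to report the
#'   precursor/mature/star sequences in the truth record.
#' @param nReads number of reads to draw.
#' @param starFraction probability that a read comes from the star arm.
#' @param matureLenRange integer(2), allowed mature read lengths (20-25 nt).
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @return A list with `reads` (`GRanges`), `truth` (read-level data.frame
#'   as in [simulateSirnaDuplexes()]; `pair_id` holds the arm) and `gene`
#'   (one-row data.frame `gene_id`, `precursor`, `mature`, `star`,
#'   `mature_count`, `star_count`, `seed`).
#' @export
simulateMirnaReads <- function(locus, genome, nReads, starFraction = 0.1,
                               matureLenRange = c(20L, 25L), seed = NULL) {
  stopifnot(is(locus, "GRanges"), length(locus) == 1L)
  nReads <- as.integer(nReads)
  if (is.na(nReads) || nReads < 0L) stop("nReads must be >= 0")
  if (starFraction < 0 || starFraction > 1)
    stop("starFraction must be in [0, 1]")
  matureLenRange <- as.integer(matureLenRange)
  .maybe_seed(seed)
  ch <- as.character(GenomeInfoDb::seqnames(locus))
  s <- BiocGenerics::start(locus); e <- BiocGenerics::end(locus)
  L <- e - s + 1L
  matureLen <- max(matureLenRange[1L] + 1L,
                   min(22L, matureLenRange[2L] - 1L))
  arm <- L %/% 3L
  if (arm < matureLen + 3L)
    stop("miRNA locus too short to host a ", matureLen, "-nt mature read")
  # mature on the 5' arm, offset 2 nt in; star = its base-pairing partner
  # on the 3' arm, displaced by the canonical 2-nt 3' overhang
  m_start <- s + 2L
  m_end <- m_start + matureLen - 1L
  st_start <- e - (m_end - s) + 2L
  st_end <- st_start + matureLen - 1L
  lid <- S4Vectors::mcols(locus)$locus_id
  if (is.null(lid)) lid <- "mirna_locus"

  precursor <- as.character(Biostrings::subseq(genome[[ch]], s, e))
  mature <- as.character(Biostrings::subseq(genome[[ch]], m_start, m_end))
  star <- as.character(Biostrings::subseq(genome[[ch]], st_start, st_end))

  if (nReads == 0L) {
    reads <- .reads_gr(character(), integer(), integer(), character(),
                       character(), integer(), GenomeInfoDb::seqlengths(locus))
    gene <- data.frame(gene_id = lid, precursor = precursor, mature = mature,
                       star = star, mature_count = 0L, star_count = 0L,
                       seed = extractSeed(mature), stringsAsFactors = FALSE)
    return(list(reads = reads, truth = .empty_truth(), gene = gene))
  }
  from_star <- stats::runif(nReads) < starFraction
  a_start <- ifelse(from_star, st_start, m_start)
  a_end <- ifelse(from_star, st_end, m_end)
  j5 <- sample(c(-1L, 0L, 1L), nReads, replace = TRUE)
  j3 <- sample(c(-1L, 0L, 1L), nReads, replace = TRUE)
  rs <- pmax(s, a_start + j5)
  re <- pmin(e, a_end + j3)
  # clamp to the configured length window
  too_short <- (re - rs + 1L) < matureLenRange[1L]
  re[too_short] <- rs[too_short] + matureLenRange[1L] - 1L
  too_long <- (re - rs + 1L) > matureLenRange[2L]
  re[too_long] <- rs[too_long] + matureLenRange[2L] - 1L
  ids <- paste0(lid, ifelse(from_star, "_star", "_mat"), seq_len(nReads))
  reads <- .reads_gr(ch, rs, re, "+", ids, rep(1L, nReads),
                     GenomeInfoDb::seqlengths(locus))
  truth <- data.frame(read_id = ids, class = "mirna", locus_id = lid,
                      pair_id = ifelse(from_star, "star", "mature"),
                      stringsAsFactors = FALSE)
  gene <- data.frame(gene_id = lid, precursor = precursor, mature = mature,
                     star = star, mature_count = sum(!from_star),
                     star_count = sum(from_star),
                     seed = extractSeed(mature), stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, gene = gene)
}

#' Simulate uniform background reads
#'
#' Reads are placed uniformly over chromosomes (proportionally to length),
#' positions and strands, with lengths uniform in `lenRange`.  This is the
#' null model for the overlap signature: background pairs hit any overlap
#' group with (approximately) equal probability.
#'
#' @param seqlens named integer vector of chromosome lengths, or a
#'   `DNAStringSet` genome.
#' @param nReads number of reads.
#' @param lenRange integer(2) read length window (default 18-35 nt).
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @return A list with `reads` (`GRanges`) and `truth` (data.frame).
#' @export
simulateBackground <- function(seqlens, nReads, lenRange = c(18L, 35L),
                               seed = NULL) {
  if (is(seqlens, "DNAStringSet")) {
    sl <- BiocGenerics::width(seqlens)
    names(sl) <- names(seqlens)
    seqlens <- sl
  }
  if (!length(seqlens) || any(seqlens <= 0L)) stop("genome must be non-empty")
  nReads <- as.integer(nReads)
  if (is.na(nReads) || nReads < 0L) stop("nReads must be >= 0")
  lenRange <- as.integer(lenRange)
  if (lenRange[1L] > lenRange[2L] || any(lenRange < 1L))
    stop("lenRange must be a positive interval with min <= max")
  if (max(lenRange) > min(seqlens))
    stop("background reads longer than the shortest chromosome")
  .maybe_seed(seed)
  if (nReads == 0L)
    return(list(reads = .reads_gr(character(), integer(), integer(),
                                  character(), character(), integer(),
                                  seqlens),
                truth = .empty_truth()))
  chrom <- names(seqlens)[sample.int(length(seqlens), nReads, replace = TRUE,
                                     prob = seqlens)]
  len <- sample(seq.int(lenRange[1L], lenRange[2L]), nReads, replace = TRUE)
  maxs <- seqlens[chrom] - len + 1L
  start <- 1L + floor(stats::runif(nReads) * maxs)
  strand <- sample(c("+", "-"), nReads, replace = TRUE)
  ids <- paste0("bg", seq_len(nReads))
  reads <- .reads_gr(chrom, start, start + len - 1L, strand, ids,
                     rep(1L, nReads), seqlens)
  truth <- data.frame(read_id = ids, class = "background",
                      locus_id = NA_character_, pair_id = NA_character_,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a complete small-RNA library under one configuration
#'
#' Runs the full generator under `config@seed` with a fixed draw order
#' (genome, then miRNA loci in order, siRNA loci, piRNA clusters,
#' background), so identical configurations give byte-identical outputs.
#' Total siRNA duplexes and ping-pong pairs are split evenly over their
#' loci.  With `multimapDuplicate = TRUE`, reads of the first siRNA locus
#' are additionally reported at the duplicated locus with `n_hits = 2`.
#'
#' @param config a [SimConfig-class].
#' @return A list: `genome` (`DNAStringSet`), `loci` (`GRanges`),
#'   `library` ([SncLibrary-class]), `truth` (read-level data.frame),
#'   `genes` (one row per simulated miRNA gene).
#' @examples
#' sim <- simulateLibrary(SimConfig(genomeLength = 30000, nMirnaLoci = 1,
#'   nSirnaLoci = 1, nPirnaClusters = 1, nMirnaReads = 50,
#'   nSirnaDuplexes = 20, nPirnaPairs = 20, nBackgroundReads = 100,
#'   seed = 7))
#' sim$library
#' @export
simulateLibrary <- function(config) {
  validObject(config)
  g <- simulateGenome(config, seed = config@seed)
  loci <- g$loci
  cls <- S4Vectors::mcols(loci)$class
  reads <- list(); truth <- list(); genes <- list()

  for (i in which(cls == "mirna")) {
    r <- simulateMirnaReads(loci[i], g$genome, config@nMirnaReads,
                            starFraction = config@starFraction,
                            matureLenRange = config@mirnaMatureLenRange,
                            seed = NULL)
    reads <- c(reads, list(r$reads)); truth <- c(truth, list(r$truth))
    genes <- c(genes, list(r$gene))
  }
  si_loci <- which(cls == "sirna")
  if (length(si_loci) && config@nSirnaDuplexes > 0L) {
    per <- .split_evenly(config@nSirnaDuplexes, length(si_loci))
    for (j in seq_along(si_loci)) {
      r <- simulateSirnaDuplexes(loci[si_loci[j]], per[j],
                                 readLen = config@sirnaReadLen,
                                 overhang = config@sirnaOverhang,
                                 seed = NULL, phased = config@phasedSirna)
      if (j == 1L && config@multimapDuplicate) {
        copy <- which(cls == "sirna_copy")[1L]
        off <- BiocGenerics::start(loci)[copy] - BiocGenerics::start(loci)[si_loci[j]]
        dup <- GenomicRanges::shift(r$reads, off)
        GenomeInfoDb::seqlevels(dup) <- GenomeInfoDb::seqlevels(r$reads)
        S4Vectors::mcols(r$reads)$n_hits <- 2L
        S4Vectors::mcols(dup)$n_hits <- 2L
        r$reads <- c(r$reads, dup)
      }
      reads <- c(reads, list(r$reads)); truth <- c(truth, list(r$truth))
    }
  }
  pi_loci <- which(cls == "pirna")
  if (length(pi_loci) && config@nPirnaPairs > 0L) {
    per <- .split_evenly(config@nPirnaPairs, length(pi_loci))
    for (j in seq_along(pi_loci)) {
      r <- simulatePingpongPairs(loci[pi_loci[j]], per[j],
                                 lenRange = config@pirnaLenRange, seed = NULL,
                                 fivePrimeBias = config@pingpongBias,
                                 genome = g$genome)
      reads <- c(reads, list(r$reads)); truth <- c(truth, list(r$truth))
    }
  }
  if (config@nBackgroundReads > 0L) {
    r <- simulateBackground(g$genome, config@nBackgroundReads,
                            lenRange = config@backgroundLenRange, seed = NULL)
    reads <- c(reads, list(r$reads)); truth <- c(truth, list(r$truth))
  }
  all_reads <- if (length(reads)) do.call(c, reads) else
    .reads_gr(character(), integer(), integer(), character(), character(),
              integer(), stats::setNames(BiocGenerics::width(g$genome),
                                         names(g$genome)))
  all_truth <- if (length(truth)) do.call(rbind, truth) else .empty_truth()
  all_genes <- if (length(genes)) do.call(rbind, genes) else NULL
  # depth counts each *read* once, not each alignment of a multimapper
  mc <- S4Vectors::mcols(all_reads)
  depth <- sum(as.numeric(mc$copies[!duplicated(mc$read_id)]))
  lib <- SncLibrary(all_reads, totalMapped = depth)
  list(genome = g$genome, loci = loci, library = lib, truth = all_truth,
       genes = all_genes)
}

.split_evenly <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  if (n %% k) out[seq_len(n %% k)] <- out[seq_len(n %% k)] + 1L
  out
}

#' Write a simulated library to SAM, FASTQ and a truth table
#'
#' Writes a headered SAM file (one record per alignment, `NH:i:` tag for
#' the alignment multiplicity, collapsed copy count encoded in the read
#' name as the `_xN` suffix), a FASTQ with one entry per distinct read
#' (constant quality `I`), and the ground-truth TSV.  Round-tripping the
#' SAM through [readAlignments()] reproduces coordinates, strand, length
#' and copies exactly.
#'
#' @param library an [SncLibrary-class].
#' @param genome `DNAStringSet` the reads were simulated from.
#' @param dir output directory (created if needed).
#' @param truth optional truth data.frame (written as `<prefix>_truth.tsv`).
#' @param prefix file name prefix (default `"library"`).
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeLibrary <- function(library, genome, dir, truth = NULL,
                         prefix = "library") {
  stopifnot(is(library, "SncLibrary"), is(genome, "DNAStringSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gr <- reads(library)
  mc <- S4Vectors::mcols(gr)
  sam_path <- file.path(dir, paste0(prefix, ".sam"))
  fq_path <- file.path(dir, paste0(prefix, ".fastq"))
  paths <- c(sam = sam_path, fastq = fq_path)

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      BiocGenerics::width(genome)))
  if (length(gr)) {
    fwd <- .read_sequences(gr, genome)   # 5'->3' read sequences
    neg <- as.character(BiocGenerics::strand(gr)) == "-"
    sam_seq <- fwd
    sam_seq[neg] <- Biostrings::reverseComplement(sam_seq[neg])  # SAM stores + strand
    qname <- paste0(mc$read_id, "_x", mc$copies)
    recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
                    qname, ifelse(neg, 16L, 0L),
                    as.character(GenomeInfoDb::seqnames(gr)),
                    BiocGenerics::start(gr), BiocGenerics::width(gr),
                    as.character(sam_seq),
                    strrep("I", BiocGenerics::width(gr)), mc$n_hits)
    writeLines(c(header, recs), sam_path)
    first <- !duplicated(mc$read_id)
    writeLines(as.vector(rbind(paste0("@", qname[first]),
                               as.character(fwd[first]),
                               "+",
                               strrep("I", BiocGenerics::width(gr)[first]))),
               fq_path)
  } else {
    writeLines(header, sam_path)
    writeLines(character(), fq_path)
  }
  if (!is.null(truth)) {
    truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' Write a simulated genome and its locus annotation
#'
#' @param genome `DNAStringSet` from [simulateGenome()].
#' @param loci `GRanges` of class-labelled loci.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Invisibly, the written paths (FASTA + BED6; BED name column is
#'   the locus id, e.g. `mirna_1`).
#' @export
writeGenomeAnnotation <- function(genome, loci, dir, prefix = "genome") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  bed <- file.path(dir, paste0(prefix, "_loci.bed"))
  Biostrings::writeXStringSet(genome, fa)
  out <- loci
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(loci)$locus_id,
    score = rep(0L, length(loci)))
  rtracklayer::export(out, bed, format = "BED")
  invisible(c(fasta = fa, bed = bed))
}
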