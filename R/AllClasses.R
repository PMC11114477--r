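#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Simulation configuration for synthetic small-RNA libraries
#'
#' `SimConfig` bundles every parameter of the synthetic-library generator:
#' genome geometry, per-class locus and read counts, and the read-length
#' conventions of the three small-RNA classes (21-nt DICER2 siRNA duplexes
#' with a 2-nt 3' overhang, 24-30 nt ping-pong piRNAs, 20-25 nt mature
#' miRNAs).  The defaults reproduce the library composition used throughout
#' the package's validation suite: a 100 kb genome carrying 5 miRNA hairpin
#' loci, 3 dsRNA (siRNA) loci and 2 piRNA clusters, expressed as 500 siRNA
#' duplexes, 500 ping-pong pairs, 1000 reads per miRNA locus and 5000
#' uniform background reads.
#'
#' @slot genomeLength integer, total genome size in bases.
#' @slot nChromosomes integer, number of chromosomes (genome split evenly).
#' @slot seed integer master PRNG seed.
#' @slot nMirnaLoci,nSirnaLoci,nPirnaClusters integer locus counts per class.
#' @slot mirnaLocusLen,sirnaLocusLen,pirnaClusterLen integer locus lengths (nt).
#' @slot nMirnaReads integer reads simulated per miRNA locus.
#' @slot nSirnaDuplexes integer total siRNA duplexes (pairs of reads).
#' @slot nPirnaPairs integer total ping-pong pairs.
#' @slot nBackgroundReads integer uniform background reads.
#' @slot sirnaReadLen integer siRNA read length (nt, default 21).
#' @slot sirnaOverhang integer 3' overhang of the duplex (nt, default 2),
#'   so partner reads overlap by `sirnaReadLen - sirnaOverhang` = 19 nt.
#' @slot pirnaLenRange integer(2) piRNA length range (default 24-30 nt).
#' @slot mirnaMatureLenRange integer(2) mature miRNA length range (20-25 nt).
#' @slot backgroundLenRange integer(2) background read length range (18-35 nt).
#' @slot starFraction numeric in [0,1], fraction of miRNA reads from the
#'   star (passenger) arm.
#' @slot phasedSirna logical; tile duplexes every read length instead of
#'   placing them uniformly at random.
#' @slot pingpongBias logical; impose a 5'-U bias on plus-strand and a
#'   position-10 A on minus-strand ping-pong reads (off by default).
#' @slot multimapDuplicate logical; duplicate the first siRNA locus elsewhere
#'   in the genome so its reads become controlled two-hit multimappers.
#'
#' @seealso [simulateLibrary()], [simulateGenome()]
#' @export
setClass("SimConfig",
  representation(
    genomeLength = "integer",
    nChromosomes = "integer",
    seed = "integer",
    nMirnaLoci = "integer",
    nSirnaLoci = "integer",
    nPirnaClusters = "integer",
    mirnaLocusLen = "integer",
    sirnaLocusLen = "integer",
    pirnaClusterLen = "integer",
    nMirnaReads = "integer",
    nSirnaDuplexes = "integer",
    nPirnaPairs = "integer",
    nBackgroundReads = "integer",
    sirnaReadLen = "integer",
    sirnaOverhang = "integer",
    pirnaLenRange = "integer",
    mirnaMatureLenRange = "integer",
    backgroundLenRange = "integer",
    starFraction = "numeric",
    phasedSirna = "logical",
    pingpongBias = "logical",
    multimapDuplicate = "logical"
  ),
  prototype(
    genomeLength = 100000L,
    nChromosomes = 1L,
    seed = 1L,
    nMirnaLoci = 5L,
    nSirnaLoci = 3L,
    nPirnaClusters = 2L,
    mirnaLocusLen = 80L,
    sirnaLocusLen = 400L,
    pirnaClusterLen = 2000L,
    nMirnaReads = 1000L,
    nSirnaDuplexes = 500L,
    nPirnaPairs = 500L,
    nBackgroundReads = 5000L,
    sirnaReadLen = 21L,
    sirnaOverhang = 2L,
    pirnaLenRange = c(24L, 30L),
    mirnaMatureLenRange = c(20L, 25L),
    backgroundLenRange = c(18L, 35L),
    starFraction = 0.1,
    phasedSirna = FALSE,
    pingpongBias = FALSE,
    multimapDuplicate = FALSE
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  scal <- c("genomeLength", "nChromosomes", "mirnaLocusLen", "sirnaLocusLen",
            "pirnaClusterLen", "sirnaReadLen", "sirnaOverhang")
  for (s in scal) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msg <- c(msg, paste0(s, " must be a single value"))
  }
  if (length(msg)) return(msg)
  if (object@genomeLength <= 0L) msg <- c(msg, "genomeLength must be > 0")
  if (object@nChromosomes <= 0L) msg <- c(msg, "nChromosomes must be > 0")
  counts <- c(nMirnaLoci = object@nMirnaLoci, nSirnaLoci = object@nSirnaLoci,
              nPirnaClusters = object@nPirnaClusters, nMirnaReads = object@nMirnaReads,
              nSirnaDuplexes = object@nSirnaDuplexes, nPirnaPairs = object@nPirnaPairs,
              nBackgroundReads = object@nBackgroundReads)
  if (any(counts < 0L)) msg <- c(msg, "locus and read counts must be >= 0")
  for (s in c("pirnaLenRange", "mirnaMatureLenRange", "backgroundLenRange")) {
    r <- slot(object, s)
    if (length(r) != 2L || any(r <= 0L) || r[1L] > r[2L])
      msg <- c(msg, paste0(s, " must be a positive interval with min <= max"))
  }
  if (object@sirnaReadLen <= 0L) msg <- c(msg, "sirnaReadLen must be > 0")
  if (object@sirnaOverhang < 0L || object@sirnaOverhang >= object@sirnaReadLen)
    msg <- c(msg, "sirnaOverhang must satisfy 0 <= overhang < sirnaReadLen")
  if (object@starFraction < 0 || object@starFraction > 1)
    msg <- c(msg, "starFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' All arguments are optional and override the class defaults, which are the
#' validation-library conditions (100 kb genome, 500 siRNA duplexes, 500
#' ping-pong pairs, 1000 reads per miRNA locus, 5000 background reads).
#'
#' @param ... named slot overrides, e.g. `SimConfig(genomeLength = 5e4,
#'   seed = 7L)`.  Numeric values for integer slots are coerced.
#' @return A validated `SimConfig` object.
#' @examples
#' cfg <- SimConfig(seed = 42L, nBackgroundReads = 1000)
#' cfg
#' @export
SimConfig <- function(...) {
  args <- list(...)
  if (length(args)) {
    slots <- getSlots("SimConfig")
    unknown <- setdiff(names(args), names(slots))
    if (length(unknown))
      stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "))
    for (nm in names(args)) {
      if (slots[[nm]] == "integer") args[[nm]] <- as.integer(args[[nm]])
    }
  }
  do.call(new, c("SimConfig", args))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@genomeLength, " b genome / ",
      object@nChromosomes, " chromosome(s), seed ", object@seed, "\n", sep = "")
  cat("  loci: ", object@nMirnaLoci, " miRNA, ", object@nSirnaLoci,
      " siRNA, ", object@nPirnaClusters, " piRNA cluster(s)\n", sep = "")
  cat("  reads: ", object@nMirnaReads, "/miRNA locus, ",
      object@nSirnaDuplexes, " siRNA duplexes, ", object@nPirnaPairs,
      " ping-pong pairs, ", object@nBackgroundReads, " background\n", sep = "")
  cat("  siRNA ", object@sirnaReadLen, " nt (overhang ", object@sirnaOverhang,
      "), piRNA ", object@pirnaLenRange[1L], "-", object@pirnaLenRange[2L],
      " nt, miRNA ", object@mirnaMatureLenRange[1L], "-",
      object@mirnaMatureLenRange[2L], " nt\n", sep = "")
  invisible(NULL)
})

#' A library of aligned small-RNA reads
#'
#' `SncLibrary` wraps a [GenomicRanges::GRanges] of collapsed small-RNA
#' alignments.  Each range is one alignment; metadata columns `read_id`
#' (character), `copies` (collapsed identical-read count, >= 1) and `n_hits`
#' (number of genomic alignments of the read, >= 1) are mandatory.
#' `totalMapped` records the library sequencing depth (sum of copies) at
#' read time, *before* any filtering, so that RPM values stay comparable
#' across parameterizations.
#'
#' @slot reads a `GRanges` with mcols `read_id`, `copies`, `n_hits`.
#' @slot totalMapped numeric, total mapped copies at read time.
#' @slot tissue character, `"ovary"`, `"soma"` or `"unspecified"`.
#'
#' @seealso [readAlignments()], [collapseReads()], [filterReads()],
#'   [rpmNormalize()]
#' @export
setClass("SncLibrary",
  representation(reads = "GRanges", totalMapped = "numeric", tissue = "character"),
  prototype(reads = GenomicRanges::GRanges(), totalMapped = 0, tissue = "unspecified")
)

setValidity("SncLibrary", function(object) {
  msg <- character()
  r <- object@reads
  need <- c("read_id", "copies", "n_hits")
  miss <- setdiff(need, colnames(S4Vectors::mcols(r)))
  if (length(miss))
    return(paste("reads are missing mcols:", paste(miss, collapse = ", ")))
  if (length(r)) {
    if (any(S4Vectors::mcols(r)$copies < 1)) msg <- c(msg, "copies must be >= 1")
    if (any(S4Vectors::mcols(r)$n_hits < 1)) msg <- c(msg, "n_hits must be >= 1")
    if (!all(as.character(BiocGenerics::strand(r)) %in% c("+", "-")))
      msg <- c(msg, "strand must be + or - for every read")
  }
  if (length(object@totalMapped) != 1L || is.na(object@totalMapped) ||
      object@totalMapped < 0)
    msg <- c(msg, "totalMapped must be a single non-negative number")
  mc <- S4Vectors::mcols(r)
  # a multimapper contributes its copies once, however many alignments it has
  if (object@totalMapped <
      sum(as.numeric(mc$copies[!duplicated(mc$read_id)])) - 1e-6)
    msg <- c(msg, "totalMapped must be >= sum of retained read copies")
  if (!object@tissue %in% c("ovary", "soma", "unspecified"))
    msg <- c(msg, "tissue must be ovary, soma or unspecified")
  if (length(msg)) msg else TRUE
})

#' Construct an [SncLibrary-class]
#'
#' @param reads `GRanges` with mcols `read_id`, `copies`, `n_hits` (missing
#'   `copies`/`n_hits` default to 1, missing `read_id` to `read1..readN`).
#' @param totalMapped library depth (sum of copies pre-filter); defaults to
#'   `sum(copies)` of `reads`.
#' @param tissue sample tissue label.
#' @return An `SncLibrary`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 121), strand = "+")
#' SncLibrary(gr)
#' @export
SncLibrary <- function(reads = GenomicRanges::GRanges(), totalMapped = NULL,
                       tissue = c("unspecified", "ovary", "soma")) {
  tissue <- match.arg(tissue)
  mc <- S4Vectors::mcols(reads)
  if (is.null(mc$read_id))
    mc$read_id <- if (length(reads)) paste0("read", seq_along(reads)) else character()
  if (is.null(mc$copies)) mc$copies <- rep(1L, length(reads))
  if (is.null(mc$n_hits)) mc$n_hits <- rep(1L, length(reads))
  S4Vectors::mcols(reads) <- mc
  if (is.null(totalMapped)) totalMapped <- sum(as.numeric(mc$copies))
  new("SncLibrary", reads = reads, totalMapped = as.numeric(totalMapped),
      tissue = tissue)
}

setMethod("show", "SncLibrary", function(object) {
  r <- object@reads
  cat("SncLibrary with ", length(r), " alignment(s), ",
      sum(S4Vectors::mcols(r)$copies), " read copies (totalMapped ",
      format(object@totalMapped, big.mark = ","), "), tissue: ",
      object@tissue, "\n", sep = "")
  if (length(r)) {
    w <- BiocGenerics::width(r)
    cat("  read lengths ", min(w), "-", max(w), " nt; ",
        sum(BiocGenerics::strand(r) == "+"), " plus / ",
        sum(BiocGenerics::strand(r) == "-"), " minus strand\n", sep = "")
  }
  invisible(NULL)
})

#' Overlap-group histogram of opposite-strand read pairs
#'
#' Counts `n_k` of plus/minus read pairs whose 5'-5' overlap equals `k`
#' nucleotides, for `k` in `[kMin, kMax]` (4-20 by default), within one
#' read-length stratum.  The map is zero-filled: there is exactly one entry
#' for every `k` in the range.
#'
#' @slot stratumLength character; the common read length of both pair
#'   members, or `"all"` for the mixed-length mode.
#' @slot kMin,kMax integer bounds of the overlap groups.
#' @slot counts named numeric vector, `counts[["k"]]` = weighted pair count.
#' @slot weighting `"copy_weighted"` (weight = product of `copies/n_hits` of
#'   the members) or `"raw_pairs"` (weight 1 per pair).
#'
#' @seealso [overlapHistogram()], [zscoreProfile()]
#' @export
setClass("OverlapHistogram",
  representation(stratumLength = "character", kMin = "integer", kMax = "integer",
                 counts = "numeric", weighting = "character"))

setValidity("OverlapHistogram", function(object) {
  msg <- character()
  ks <- seq.int(object@kMin, object@kMax)
  if (object@kMin > object@kMax) msg <- c(msg, "kMin must be <= kMax")
  else {
    if (length(object@counts) != length(ks) ||
        !identical(names(object@counts), as.character(ks)))
      msg <- c(msg, "counts must be zero-filled and named kMin..kMax")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  }
  if (!object@weighting %in% c("copy_weighted", "raw_pairs"))
    msg <- c(msg, "weighting must be copy_weighted or raw_pairs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapHistogram", function(object) {
  cat("OverlapHistogram (stratum ", object@stratumLength, " nt, k ",
      object@kMin, "..", object@kMax, ", ", object@weighting, ")\n", sep = "")
  print(round(object@counts, 3))
  invisible(NULL)
})

#' Standardized Z-score profile over overlap groups
#'
#' Each overlap-group count is standardized against the mean and population
#' standard deviation of all groups in the histogram:
#' `z_k = (n_k - mean) / sd`.  A Z-score above 1 means that pairs with that
#' overlap are at least one standard deviation more numerous than the
#' average overlap group.  When all counts are equal (`sd == 0`) the profile
#' is flagged `degenerate` and every `z_k` is 0.
#'
#' @slot z named numeric vector of standardized scores.
#' @slot mean,sd numeric; moments of the counts over the overlap groups
#'   (population sd, i.e. divisor `n`).
#' @slot degenerate logical, `TRUE` when `sd == 0`.
#' @slot stratumLength character, inherited from the histogram.
#'
#' @seealso [zscoreProfile()], [callSignatures()]
#' @export
setClass("ZScoreProfile",
  representation(z = "numeric", mean = "numeric", sd = "numeric",
                 degenerate = "logical", stratumLength = "character"))

setValidity("ZScoreProfile", function(object) {
  msg <- character()
  if (object@degenerate && any(object@z != 0))
    msg <- c(msg, "degenerate profile must have all z = 0")
  if (!object@degenerate && length(object@z) &&
      abs(sum(object@z)) > 1e-9 * max(1, length(object@z)))
    msg <- c(msg, "z-scores must sum to 0 when not degenerate")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ZScoreProfile", function(object) {
  cat("ZScoreProfile (stratum ", object@stratumLength, " nt; mean ",
      signif(object@mean, 4), ", sd ", signif(object@sd, 4),
      if (object@degenerate) ", degenerate" else "", ")\n", sep = "")
  print(round(object@z, 3))
  invisible(NULL)
})
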