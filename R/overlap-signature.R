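#' 5'-5' overlap of an opposite-strand read pair
#'
#' For a plus-strand read and a minus-strand read on the same chromosome,
#' the overlap is the distance from the plus read's 5' end (its start) to
#' the minus read's 5' end (its end), inclusive:
#' `end(minus) - start(plus) + 1` in 1-based closed coordinates.  A 21-nt
#' DICER2 duplex with a 2-nt 3' overhang gives 19; a ping-pong piRNA pair
#' gives 10.  The value may be zero or negative when the minus 5' end lies
#' upstream of the plus 5' end; a pair counts as "overlapping by k" for
#' signature purposes only when `1 <= k <= min(length(plus), length(minus))`
#' (then k equals the length of the interval intersection).
#'
#' @param plusRead,minusRead `GRanges` of equal length (element-wise pairs);
#'   strands must be `+` and `-` respectively, chromosomes must match.
#' @return Integer vector of 5'-5' overlaps.
#' @examples
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 121), strand = "+")
#' m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99, 119), strand = "-")
#' pairOverlap(p, m)   # 19
#' @export
pairOverlap <- function(plusRead, minusRead) {
  stopifnot(is(plusRead, "GRanges"), is(minusRead, "GRanges"),
            length(plusRead) == length(minusRead))
  if (!all(as.character(BiocGenerics::strand(plusRead)) == "+"))
    stop("plusRead must be entirely on the + strand")
  if (!all(as.character(BiocGenerics::strand(minusRead)) == "-"))
    stop("minusRead must be entirely on the - strand")
  if (!all(as.character(GenomeInfoDb::seqnames(plusRead)) ==
           as.character(GenomeInfoDb::seqnames(minusRead))))
    stop("paired reads must be on the same chromosome")
  as.integer(BiocGenerics::end(minusRead) - BiocGenerics::start(plusRead) + 1L)
}

#' Histogram of read-pair overlaps over groups k = kMin..kMax
#'
#' Enumerates every plus/minus read pair of the library that lies on the
#' same chromosome, belongs to the requested read-length stratum
#' (both members of length `stratumLength`, or any length for `"all"`),
#' and whose 5'-5' overlap `k` satisfies
#' `max(kMin, 1) <= k <= min(kMax, length(plus), length(minus))`.
#' Each qualifying pair adds its weight to `n_k`: 1 under `"raw_pairs"`, or
#' the product of the members' `copies / n_hits` under `"copy_weighted"`
#' (the default; fractional multimapper weighting avoids inflating the
#' histogram with reads that align up to 100 times).  Pairs are unordered
#' and counted once; a read is never paired with itself.
#'
#' The implementation buckets plus 5' ends and minus 5' ends by genomic
#' position and, for each k, multiplies the bucketed weight sums, which is
#' exactly equivalent to the quadratic all-pairs enumeration.
#'
#' @param library an [SncLibrary-class].
#' @param stratumLength integer read length of both pair members, or
#'   `"all"` for the mixed-length mode (used for the 24-30 nt ping-pong
#'   stratum after [filterReads()]).
#' @param kMin,kMax integer overlap-group bounds (defaults 4 and 20).
#' @param weighting `"copy_weighted"` or `"raw_pairs"`.
#' @return An [OverlapHistogram-class].
#' @examples
#' locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
#' dup <- simulateSirnaDuplexes(locus, 50, seed = 1)
#' h <- overlapHistogram(SncLibrary(dup$reads), stratumLength = 21)
#' h
#' @export
overlapHistogram <- function(library, stratumLength = 21L, kMin = 4L,
                             kMax = 20L,
                             weighting = c("copy_weighted", "raw_pairs")) {
  stopifnot(is(library, "SncLibrary"))
  weighting <- match.arg(weighting)
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (kMin > kMax) stop("kMin must be <= kMax")
  ks <- seq.int(kMin, kMax)
  counts <- stats::setNames(numeric(length(ks)), as.character(ks))
  gr <- reads(library)
  all_strata <- identical(stratumLength, "all")
  if (!all_strata) {
    stratumLength <- as.integer(stratumLength)
    gr <- gr[BiocGenerics::width(gr) == stratumLength]
  }
  strand <- as.character(BiocGenerics::strand(gr))
  plus <- gr[strand == "+"]; minus <- gr[strand == "-"]
  if (length(plus) && length(minus)) {
    wp <- .read_weights(plus, weighting)
    wm <- .read_weights(minus, weighting)
    chr_p <- as.character(GenomeInfoDb::seqnames(plus))
    chr_m <- as.character(GenomeInfoDb::seqnames(minus))
    len_p <- BiocGenerics::width(plus); len_m <- BiocGenerics::width(minus)
    p5 <- BiocGenerics::start(plus); m5 <- BiocGenerics::end(minus)
    for (k in ks) {
      if (k < 1L) next
      sel_p <- len_p >= k; sel_m <- len_m >= k
      if (!any(sel_p) || !any(sel_m)) next
      # pair (p, m) overlaps by k iff m's 5' end == p's 5' end + k - 1
      key_p <- paste0(chr_p[sel_p], ":", p5[sel_p] + k - 1L)
      key_m <- paste0(chr_m[sel_m], ":", m5[sel_m])
      sp <- rowsum(wp[sel_p], key_p)
      sm <- rowsum(wm[sel_m], key_m)
      common <- intersect(rownames(sp), rownames(sm))
      if (length(common))
        counts[[as.character(k)]] <- sum(sp[common, 1L] * sm[common, 1L])
    }
  }
  new("OverlapHistogram",
      stratumLength = if (all_strata) "all" else as.character(stratumLength),
      kMin = kMin, kMax = kMax, counts = counts, weighting = weighting)
}

#' Z-score profile of an overlap histogram
#'
#' Standardizes the overlap-group counts against their own mean and
#' population standard deviation (divisor `n`, the number of overlap
#' groups): `z_k = (n_k - mean) / sd`.  A score of 1 for group k means the
#' pairs overlapping by k nt are one standard deviation more numerous than
#' the average overlap group of the stratum.  When all groups are equal
#' (`sd = 0`, e.g. an empty library) the profile is degenerate and every
#' `z_k` is 0.
#'
#' @param x an [OverlapHistogram-class].
#' @return A [ZScoreProfile-class].
#' @examples
#' h <- new("OverlapHistogram", stratumLength = "21", kMin = 4L, kMax = 20L,
#'          counts = stats::setNames(c(rep(1, 15), 18, 1), as.character(4:20)),
#'          weighting = "raw_pairs")
#' zscoreProfile(h)   # mean 2, sd 4, peak z = 4
#' @rdname zscoreProfile
#' @export
setMethod("zscoreProfile", "OverlapHistogram", function(x) {
  n <- x@counts
  m <- mean(n)
  s <- sqrt(mean((n - m)^2))
  if (s == 0) {
    z <- stats::setNames(numeric(length(n)), names(n))
    return(new("ZScoreProfile", z = z, mean = m, sd = 0,
               degenerate = TRUE, stratumLength = x@stratumLength))
  }
  new("ZScoreProfile", z = (n - m) / s, mean = m, sd = s,
      degenerate = FALSE, stratumLength = x@stratumLength)
})

#' Call the Dicer and ping-pong signatures from a Z-score profile
#'
#' The Dicer (endo-siRNA) signature for a read-length stratum L is an
#' excess of pairs overlapping by `L - 2` nt (the duplex geometry with
#' 2-nt 3' overhangs); the ping-pong piRNA signature is an excess at 10
#' nt.  Each signature is called present when its `z_k` exceeds the
#' threshold (default 1: at least one standard deviation above the mean
#' overlap group).  Degenerate profiles call both signatures absent.
#'
#' @param profile a [ZScoreProfile-class].
#' @param stratumLength integer read length L of the stratum (defines the
#'   Dicer overlap `L - 2`); defaults to the profile's stratum when that is
#'   numeric.
#' @param threshold Z-score threshold (default 1).
#' @return A two-row data.frame: `signature` (`dicer`, `pingpong`),
#'   `stratum_length`, `overlap_k`, `z_value`, `present`.
#' @export
callSignatures <- function(profile, stratumLength = NULL, threshold = 1) {
  stopifnot(is(profile, "ZScoreProfile"))
  if (is.null(stratumLength)) {
    if (profile@stratumLength == "all")
      stop("stratumLength must be given for a mixed-length profile")
    stratumLength <- as.integer(profile@stratumLength)
  }
  stratumLength <- as.integer(stratumLength)
  ks <- as.integer(names(profile@z))
  need <- c(dicer = stratumLength - 2L, pingpong = 10L)
  missing_k <- need[!need %in% ks]
  if (length(missing_k))
    stop("overlap group(s) ", paste(missing_k, collapse = ", "),
         " outside the histogram range [", min(ks), ", ", max(ks), "]")
  z <- profile@z[as.character(need)]
  data.frame(signature = names(need),
             stratum_length = stratumLength,
             overlap_k = unname(need),
             z_value = unname(z),
             present = !profile@degenerate & unname(z) > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signature table across libraries
#'
#' Computes the Z-score profile of every library in the requested stratum
#' and the Dicer/ping-pong calls, one row per library, ordered by library
#' name (so reruns are byte-identical).
#'
#' @param libraries a *named* list of [SncLibrary-class] objects.
#' @param stratumLength stratum read length (default 21).
#' @param kMin,kMax overlap-group range (defaults 4, 20).
#' @param threshold Z-score call threshold (default 1).
#' @param weighting pair weighting, see [overlapHistogram()].
#' @param file optional path; when given the table is also written as TSV.
#' @return A data.frame with columns `library`, `z_4`..`z_20`, `dicer_z`,
#'   `dicer_present`, `pingpong_z`, `pingpong_present`.
#' @export
signatureTable <- function(libraries, stratumLength = 21L, kMin = 4L,
                           kMax = 20L, threshold = 1,
                           weighting = c("copy_weighted", "raw_pairs"),
                           file = NULL) {
  weighting <- match.arg(weighting)
  if (!length(libraries)) stop("at least one library is required")
  if (is.null(names(libraries)) || anyNA(names(libraries)) ||
      any(names(libraries) == ""))
    stop("libraries must be a named list")
  nm <- sort(names(libraries))
  rows <- lapply(nm, function(n) {
    h <- overlapHistogram(libraries[[n]], stratumLength = stratumLength,
                          kMin = kMin, kMax = kMax, weighting = weighting)
    z <- zscoreProfile(h)
    calls <- callSignatures(z, stratumLength = stratumLength,
                            threshold = threshold)
    zrow <- as.data.frame(as.list(stats::setNames(
      z@z, paste0("z_", names(z@z)))), check.names = FALSE)
    cbind(data.frame(library = n, stringsAsFactors = FALSE), zrow,
          data.frame(dicer_z = calls$z_value[calls$signature == "dicer"],
                     dicer_present = calls$present[calls$signature == "dicer"],
                     pingpong_z = calls$z_value[calls$signature == "pingpong"],
                     pingpong_present = calls$present[calls$signature == "pingpong"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
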