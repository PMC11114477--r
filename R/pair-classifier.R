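.empty_pairs <- function() {
  data.frame(class = character(), chrom = character(),
             plus_id = character(), minus_id = character(),
             plus_start = integer(), plus_end = integer(),
             minus_start = integer(), minus_end = integer(),
             overlap = integer(), cov_plus = integer(),
             cov_minus = integer(), log_ratio = numeric(),
             stringsAsFactors = FALSE)
}

#' Predict candidate siRNA / piRNA read pairs from overlaps
#'
#' Candidate endo-siRNA pairs are opposite-strand pairs of equal read
#' length L (within `lengthWindow`, default 21 nt only) whose 5'-5'
#' overlap is exactly `L - 2` — the DICER2 duplex geometry.  Candidate
#' piRNA pairs have both member lengths inside the window (default 24-30
#' nt) and an overlap of exactly 10 nt — the ping-pong geometry.  Member
#' coverages are the collapsed copy counts, and
#' `log_ratio = log2(cov_plus / cov_minus)`.
#'
#' @param library an [SncLibrary-class].
#' @param class `"sirna"` or `"pirna"`.
#' @param lengthWindow integer(2) member length window; defaults
#'   `c(21, 21)` for siRNA and `c(24, 30)` for piRNA.
#' @param requireEqualLengths logical; siRNA pairs must have equal member
#'   lengths (default TRUE — the `L - 2` rule presupposes a common L).
#' @return A data.frame, one row per candidate pair: `class`, `chrom`,
#'   member ids/coordinates, `overlap`, `cov_plus`, `cov_minus`,
#'   `log_ratio`.
#' @examples
#' locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
#' dup <- simulateSirnaDuplexes(locus, 5, seed = 1)
#' findCandidatePairs(SncLibrary(dup$reads), "sirna")
#' @export
findCandidatePairs <- function(library, class = c("sirna", "pirna"),
                               lengthWindow = NULL,
                               requireEqualLengths = TRUE) {
  stopifnot(is(library, "SncLibrary"))
  class <- match.arg(class)
  if (is.null(lengthWindow))
    lengthWindow <- if (class == "sirna") c(21L, 21L) else c(24L, 30L)
  lengthWindow <- as.integer(lengthWindow)
  if (length(lengthWindow) != 2L || lengthWindow[1L] > lengthWindow[2L])
    stop("lengthWindow must be an interval with min <= max")
  gr <- reads(library)
  w <- BiocGenerics::width(gr)
  gr <- gr[w >= lengthWindow[1L] & w <= lengthWindow[2L]]
  strand <- as.character(BiocGenerics::strand(gr))
  plus <- gr[strand == "+"]; minus <- gr[strand == "-"]
  if (!length(plus) || !length(minus)) return(.empty_pairs())

  hits <- list()
  if (class == "sirna" && requireEqualLengths) {
    for (L in seq.int(lengthWindow[1L], lengthWindow[2L])) {
      p <- plus[BiocGenerics::width(plus) == L]
      m <- minus[BiocGenerics::width(minus) == L]
      hits <- c(hits, list(.match_pairs(p, m, L - 2L)))
    }
  } else if (class == "sirna") {
    # relaxed mode: overlap must equal min(member lengths) - 2
    for (L in seq.int(lengthWindow[1L], lengthWindow[2L])) {
      p <- plus[BiocGenerics::width(plus) >= L]
      m <- minus[BiocGenerics::width(minus) >= L]
      cand <- .match_pairs(p, m, L - 2L)
      if (nrow(cand)) {
        minlen <- pmin(cand$plus_end - cand$plus_start + 1L,
                       cand$minus_end - cand$minus_start + 1L)
        cand <- cand[minlen == L, , drop = FALSE]
      }
      hits <- c(hits, list(cand))
    }
  } else {
    hits <- list(.match_pairs(plus, minus, 10L))
  }
  out <- do.call(rbind, hits)
  if (!nrow(out)) return(.empty_pairs())
  out <- cbind(class = class, out, stringsAsFactors = FALSE)
  out$log_ratio <- log2(out$cov_plus / out$cov_minus)
  rownames(out) <- NULL
  out
}

# All (plus, minus) pairs on the same chromosome with 5'-5' overlap k.
.match_pairs <- function(plus, minus, k) {
  empty <- .empty_pairs()[setdiff(names(.empty_pairs()),
                                  c("class", "log_ratio"))]
  if (!length(plus) || !length(minus) || k < 1L) return(empty)
  dfp <- data.frame(
    key = paste0(as.character(GenomeInfoDb::seqnames(plus)), ":",
                 BiocGenerics::start(plus) + k - 1L),
    plus_id = S4Vectors::mcols(plus)$read_id,
    plus_start = BiocGenerics::start(plus),
    plus_end = BiocGenerics::end(plus),
    cov_plus = as.integer(S4Vectors::mcols(plus)$copies),
    stringsAsFactors = FALSE)
  dfm <- data.frame(
    key = paste0(as.character(GenomeInfoDb::seqnames(minus)), ":",
                 BiocGenerics::end(minus)),
    minus_id = S4Vectors::mcols(minus)$read_id,
    minus_start = BiocGenerics::start(minus),
    minus_end = BiocGenerics::end(minus),
    cov_minus = as.integer(S4Vectors::mcols(minus)$copies),
    stringsAsFactors = FALSE)
  mg <- merge(dfp, dfm, by = "key")
  if (!nrow(mg)) return(empty)
  minlen <- pmin(mg$plus_end - mg$plus_start + 1L,
                 mg$minus_end - mg$minus_start + 1L)
  mg <- mg[k <= minlen, , drop = FALSE]
  if (!nrow(mg)) return(empty)
  data.frame(chrom = sub(":[0-9]+$", "", mg$key),
             plus_id = mg$plus_id, minus_id = mg$minus_id,
             plus_start = mg$plus_start, plus_end = mg$plus_end,
             minus_start = mg$minus_start, minus_end = mg$minus_end,
             overlap = rep(as.integer(k), nrow(mg)),
             cov_plus = mg$cov_plus, cov_minus = mg$cov_minus,
             stringsAsFactors = FALSE)
}

#' Apply the discard filters to candidate pairs
#'
#' A pair is discarded when (in this order, first failing reason recorded)
#' (1) either member's coverage is lower than `minCoverage` (default 5
#' reads), (2) the absolute log2 coverage ratio of the pair exceeds
#' `maxAbsLogRatio` (default 1.5), or (3) either member's interval
#' intersects an annotated miRNA region by at least 1 nt.
#'
#' @param pairs data.frame from [findCandidatePairs()].
#' @param minCoverage minimum member coverage (>= 1).
#' @param maxAbsLogRatio bound on `|log2(cov_plus / cov_minus)|`.
#' @param mirnaRegions `GRanges` of annotated miRNA loci (possibly empty).
#' @return `pairs` with added columns `status` (`kept`/`discarded`) and
#'   `discard_reason` (`low_coverage`, `log_ratio`, `mirna_region`,
#'   `none`).
#' @examples
#' locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
#' dup <- simulateSirnaDuplexes(locus, 5, seed = 1)
#' cand <- findCandidatePairs(SncLibrary(dup$reads), "sirna")
#' table(filterPairs(cand)$status)
#' @export
filterPairs <- function(pairs, minCoverage = 5L, maxAbsLogRatio = 1.5,
                        mirnaRegions = GenomicRanges::GRanges()) {
  if (minCoverage < 1L) stop("minCoverage must be >= 1")
  if (maxAbsLogRatio < 0) stop("maxAbsLogRatio must be >= 0")
  if (!nrow(pairs)) {
    pairs$status <- character(); pairs$discard_reason <- character()
    return(pairs)
  }
  reason <- rep("none", nrow(pairs))
  low_cov <- pmin(pairs$cov_plus, pairs$cov_minus) < minCoverage
  reason[low_cov] <- "low_coverage"
  bad_ratio <- reason == "none" & abs(pairs$log_ratio) > maxAbsLogRatio
  reason[bad_ratio] <- "log_ratio"
  if (length(mirnaRegions)) {
    pgr <- GenomicRanges::GRanges(pairs$chrom,
                                  IRanges::IRanges(pairs$plus_start, pairs$plus_end))
    mgr <- GenomicRanges::GRanges(pairs$chrom,
                                  IRanges::IRanges(pairs$minus_start, pairs$minus_end))
    in_mir <- GenomicRanges::countOverlaps(pgr, mirnaRegions, minoverlap = 1L) > 0L |
      GenomicRanges::countOverlaps(mgr, mirnaRegions, minoverlap = 1L) > 0L
    reason[reason == "none" & in_mir] <- "mirna_region"
  }
  pairs$status <- ifelse(reason == "none", "kept", "discarded")
  pairs$discard_reason <- reason
  pairs
}

#' Per-class, per-length RPM expression profile
#'
#' Assigns every read of the library to a small-RNA class — `mirna` when
#' its interval intersects an annotated miRNA locus, otherwise `sirna` or
#' `pirna` when it is a member of a kept pair of that class, otherwise
#' `unclassified` — and sums RPM per class and read length.  A read
#' eligible for several classes is assigned by the precedence
#' miRNA > siRNA > piRNA (reported with a message).
#'
#' @param library an [SncLibrary-class] with `totalMapped > 0`.
#' @param keptPairs data.frame of filtered pairs ([filterPairs()] output,
#'   possibly both classes rbind-ed); only rows with `status == "kept"`
#'   are used.
#' @param mirnaAnnotations `GRanges` of miRNA loci.
#' @param includeUnclassified also emit the `unclassified` rows
#'   (default FALSE).
#' @return A data.frame `class`, `length`, `rpm`, sorted by class then
#'   length.
#' @export
classLengthProfile <- function(library, keptPairs = NULL,
                               mirnaAnnotations = GenomicRanges::GRanges(),
                               includeUnclassified = FALSE) {
  stopifnot(is(library, "SncLibrary"))
  gr <- reads(library)
  if (!length(gr))
    return(data.frame(class = character(), length = integer(),
                      rpm = numeric(), stringsAsFactors = FALSE))
  rpm <- 1e6 * as.numeric(S4Vectors::mcols(gr)$copies) / totalMapped(library)
  id <- S4Vectors::mcols(gr)$read_id
  is_mir <- if (length(mirnaAnnotations))
    GenomicRanges::countOverlaps(gr, mirnaAnnotations, minoverlap = 1L,
                                 ignore.strand = TRUE) > 0L
  else rep(FALSE, length(gr))
  kept <- if (!is.null(keptPairs) && nrow(keptPairs))
    keptPairs[keptPairs$status == "kept", , drop = FALSE]
  else .empty_pairs()
  si_ids <- unique(c(kept$plus_id[kept$class == "sirna"],
                     kept$minus_id[kept$class == "sirna"]))
  pi_ids <- unique(c(kept$plus_id[kept$class == "pirna"],
                     kept$minus_id[kept$class == "pirna"]))
  cls <- rep("unclassified", length(gr))
  cls[id %in% pi_ids] <- "pirna"
  cls[id %in% si_ids] <- "sirna"
  cls[is_mir] <- "mirna"
  multi <- sum((is_mir & id %in% c(si_ids, pi_ids)) |
                 (id %in% si_ids & id %in% pi_ids))
  if (multi > 0L)
    message(multi, " read(s) eligible for several classes; ",
            "assigned by precedence miRNA > siRNA > piRNA")
  df <- data.frame(class = cls, length = BiocGenerics::width(gr), rpm = rpm,
                   stringsAsFactors = FALSE)
  if (!includeUnclassified)
    df <- df[df$class != "unclassified", , drop = FALSE]
  if (!nrow(df))
    return(data.frame(class = character(), length = integer(),
                      rpm = numeric(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(rpm ~ class + length, data = df, FUN = sum)
  agg <- agg[order(agg$class, agg$length), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Descriptive per-class tissue comparison
#'
#' Compares total per-class RPM between an ovary and a somatic library as
#' `log2((rpm_ovary + p) / (rpm_soma + p))` with pseudocount `p` (default
#' 1), which keeps the fold change finite when a class is absent from one
#' tissue.  This is a descriptive summary, not a statistical test.
#'
#' @param profileOvary,profileSoma data.frames from
#'   [classLengthProfile()], built with the same length windows.
#' @param pseudocount numeric pseudocount `p`.
#' @return A data.frame `class`, `rpm_ovary`, `rpm_soma`, `log2_fc`.
#' @export
compareTissues <- function(profileOvary, profileSoma, pseudocount = 1) {
  tot <- function(p) if (nrow(p)) tapply(p$rpm, p$class, sum) else
    stats::setNames(numeric(0), character(0))
  to <- tot(profileOvary); ts <- tot(profileSoma)
  classes <- sort(union(names(to), names(ts)))
  ov <- ifelse(classes %in% names(to), to[classes], 0)
  so <- ifelse(classes %in% names(ts), ts[classes], 0)
  data.frame(class = classes, rpm_ovary = as.numeric(ov),
             rpm_soma = as.numeric(so),
             log2_fc = log2((as.numeric(ov) + pseudocount) /
                              (as.numeric(so) + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}
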