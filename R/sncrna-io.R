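#' Read aligned small-RNA reads into an SncLibrary
#'
#' Parses a SAM file (via Rsamtools; the `NH` tag is taken as the number
#' of genomic alignments of the read, defaulting to 1) or a BED6 file
#' (score column = collapsed copy count).  Collapsed copy counts in SAM
#' are recovered from the FASTA-collapser style `_xN` read-name suffix,
#' falling back to 1.  Unmapped SAM records are dropped with a message.
#' `totalMapped` is fixed here, before any filtering, as the sum of copies
#' over distinct read ids, so RPM values are comparable across downstream
#' parameterizations.
#'
#' @param path path to the alignment file.
#' @param format `"sam"` or `"bed6"`.
#' @param tissue optional tissue label (`"ovary"`, `"soma"`,
#'   `"unspecified"`).
#' @return An [SncLibrary-class].
#' @examples
#' sim <- simulateLibrary(SimConfig(genomeLength = 20000, nMirnaLoci = 1,
#'   nSirnaLoci = 1, nPirnaClusters = 0, nMirnaReads = 20,
#'   nSirnaDuplexes = 10, nBackgroundReads = 50, seed = 3))
#' dir <- tempfile(); paths <- writeLibrary(sim$library, sim$genome, dir)
#' lib <- readAlignments(paths[["sam"]], "sam")
#' lib
#' @export
readAlignments <- function(path, format = c("sam", "bed6"),
                           tissue = c("unspecified", "ovary", "soma")) {
  format <- match.arg(format)
  tissue <- match.arg(tissue)
  .stop_if_empty_file(path)
  if (format == "sam") {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    n_unmapped <- length(Rsamtools::scanBam(
      bam, param = Rsamtools::ScanBamParam(
        what = "qname",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))[[1L]]$qname)
    if (n_unmapped > 0L)
      message("dropped ", n_unmapped, " unmapped record(s) from ", path)
    aln <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(what = "qname", tag = "NH"))
    # htslib skips records it cannot parse; insist every body line survived
    body <- which(!startsWith(readLines(path), "@"))
    n_parsed <- length(aln) + n_unmapped
    if (length(body) != n_parsed)
      stop("malformed SAM file '", path, "': ",
           length(body) - n_parsed, " record(s) failed to parse",
           .first_bad_sam_line(path), call. = FALSE)
    gr <- GenomicRanges::granges(aln)
    qn <- S4Vectors::mcols(aln)$qname
    nh <- S4Vectors::mcols(aln)$NH
    nh[is.na(nh)] <- 1L
    has_x <- grepl("_x[0-9]+$", qn)
    copies <- rep(1L, length(qn))
    copies[has_x] <- as.integer(sub(".*_x([0-9]+)$", "\\1", qn[has_x]))
    read_id <- sub("_x[0-9]+$", "", qn)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      read_id = read_id, copies = copies, n_hits = as.integer(nh))
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("malformed BED6 file '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$score) || anyNA(mc$score))
      stop("BED6 input requires a numeric score column (copy count)")
    if (any(mc$score < 1))
      stop("BED6 score column must be >= 1 to encode copy counts")
    if (!all(as.character(BiocGenerics::strand(gr)) %in% c("+", "-")))
      stop("BED6 input requires an explicit +/- strand for every record")
    nm <- mc$name
    if (is.null(nm)) nm <- paste0("read", seq_along(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      read_id = nm, copies = as.integer(mc$score),
      n_hits = rep(1L, length(gr)))
  }
  mc <- S4Vectors::mcols(gr)
  depth <- sum(as.numeric(mc$copies[!duplicated(mc$read_id)]))
  SncLibrary(gr, totalMapped = depth, tissue = tissue)
}

# Locate the first SAM body line failing basic field checks, for error
# reporting ("" when the culprit cannot be pinpointed).
.first_bad_sam_line <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "@")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    ok <- length(f) >= 11L &&
      grepl("^[0-9]+$", f[2L]) && grepl("^-?[0-9]+$", f[4L])
    if (ok && f[10L] != "*" && f[6L] != "*") {
      qlen <- sum(as.integer(regmatches(
        f[6L], gregexpr("[0-9]+(?=[MIS=X])", f[6L], perl = TRUE))[[1L]]))
      ok <- qlen == nchar(f[10L])
    }
    if (!ok) return(paste0(" (first malformed record at line ", i, ")"))
  }
  ""
}

#' Collapse identical alignments
#'
#' Merges reads identical in (chromosome, start, end, strand), summing
#' their copy counts.  Alignment multiplicities of merged reads must agree
#' (they describe the same sequence); a conflict is an error.  The
#' operation is idempotent and conserves both total copies and
#' `totalMapped`.
#'
#' @param library an [SncLibrary-class].
#' @return A collapsed [SncLibrary-class].
#' @export
collapseReads <- function(library) {
  stopifnot(is(library, "SncLibrary"))
  gr <- reads(library)
  if (!length(gr)) return(library)
  key <- paste(GenomeInfoDb::seqnames(gr), BiocGenerics::start(gr),
               BiocGenerics::end(gr), BiocGenerics::strand(gr), sep = ":")
  mc <- S4Vectors::mcols(gr)
  nh_range <- tapply(mc$n_hits, key, function(x) length(unique(x)))
  if (any(nh_range > 1L))
    stop("conflicting n_hits among identical reads at ",
         names(nh_range)[which(nh_range > 1L)[1L]])
  first <- !duplicated(key)
  out <- gr[first]
  csum <- tapply(as.numeric(mc$copies), key, sum)
  S4Vectors::mcols(out)$copies <- as.integer(csum[key[first]])
  SncLibrary(out, totalMapped = totalMapped(library), tissue = tissue(library))
}

#' Filter reads by length and alignment multiplicity
#'
#' Retains reads whose length lies in `[minLen, maxLen]` and whose number
#' of genomic alignments does not exceed `maxHits` (default 100, the
#' conventional multimapper cap for small-RNA mapping).  `totalMapped` is
#' left untouched: it records the pre-filter depth.
#'
#' @param library an [SncLibrary-class].
#' @param minLen,maxLen read length window in nt.
#' @param maxHits maximum allowed alignment multiplicity.
#' @return A filtered [SncLibrary-class].
#' @export
filterReads <- function(library, minLen = 18L, maxLen = 35L, maxHits = 100L) {
  stopifnot(is(library, "SncLibrary"))
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  if (maxHits < 1L) stop("maxHits must be >= 1")
  gr <- reads(library)
  w <- BiocGenerics::width(gr)
  keep <- w >= minLen & w <= maxLen & S4Vectors::mcols(gr)$n_hits <= maxHits
  SncLibrary(gr[keep], totalMapped = totalMapped(library),
             tissue = tissue(library))
}

#' Read locus annotations (BED6 or GFF3)
#'
#' Returns annotated intervals as a `GRanges` with a `class` metadata
#' column (BED name column, or the GFF3 feature type).  Overlapping
#' annotations are retained as-is, never merged.  GFF3's 1-based inclusive
#' coordinates and BED's 0-based half-open coordinates are both mapped to
#' the 1-based closed `GRanges` convention by rtracklayer.
#'
#' @param path annotation file path.
#' @param format `"bed6"` or `"gff3"`.
#' @return A `GRanges` with mcol `class`.
#' @export
readAnnotations <- function(path, format = c("bed6", "gff3")) {
  format <- match.arg(format)
  .stop_if_empty_file(path)
  fmt <- if (format == "bed6") "BED" else "GFF3"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("malformed ", format, " file '",
                                          path, "': ", conditionMessage(e),
                                          call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  cls <- if (format == "bed6") mc$name else as.character(mc$type)
  if (is.null(cls)) cls <- rep(NA_character_, length(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(class = cls)
  gr
}

#' Per-read RPM values
#'
#' Reads-per-million normalization against the library's pre-filter mapped
#' depth: `rpm = 1e6 * copies / totalMapped`.  Summed over an unfiltered
#' unique-mapper library this is exactly 1e6.
#'
#' @param library an [SncLibrary-class] with `totalMapped > 0`.
#' @return A numeric vector of RPM values, named by read id.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 21), strand = "+",
#'                              read_id = "r1", copies = 50L, n_hits = 1L)
#' rpmNormalize(SncLibrary(gr, totalMapped = 2e6))   # 25
#' @export
rpmNormalize <- function(library) {
  stopifnot(is(library, "SncLibrary"))
  if (totalMapped(library) <= 0)
    stop("totalMapped is 0: cannot normalize an empty library")
  mc <- S4Vectors::mcols(reads(library))
  stats::setNames(1e6 * as.numeric(mc$copies) / totalMapped(library),
                  mc$read_id)
}
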