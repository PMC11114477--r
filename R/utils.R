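# Internal helpers shared across modules.

# Set the PRNG only when an explicit seed is given; inside simulateLibrary()
# the master seed is set once and the stage draws consume the stream in a
# fixed, documented order.
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Normalize an RNA/DNA string to the DNA alphabet used internally.
.norm_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Read weights under the two pairing-weight policies.
.read_weights <- function(gr, weighting) {
  mc <- S4Vectors::mcols(gr)
  if (weighting == "copy_weighted") as.numeric(mc$copies) / as.numeric(mc$n_hits)
  else rep(1, length(gr))
}

# 5' end of a read in 1-based coordinates: start on +, end on -.
.five_prime <- function(gr) {
  ifelse(as.character(BiocGenerics::strand(gr)) == "+",
         BiocGenerics::start(gr), BiocGenerics::end(gr))
}

.stop_if_empty_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  invisible(NULL)
}

# Extract read sequences (5'->3') from a genome DNAStringSet given a GRanges.
.read_sequences <- function(gr, genome) {
  if (!length(gr)) return(Biostrings::DNAStringSet())
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- setdiff(unique(chroms), names(genome))
  if (length(bad))
    stop("reads reference chromosome(s) absent from the genome: ",
         paste(bad, collapse = ", "))
  out <- vector("list", length(gr))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    seqs <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(BiocGenerics::start(gr)[idx], BiocGenerics::end(gr)[idx]))
    out[idx] <- as.list(seqs)
  }
  ss <- Biostrings::DNAStringSet(out)
  neg <- as.character(BiocGenerics::strand(gr)) == "-"
  if (any(neg)) ss[neg] <- Biostrings::reverseComplement(ss[neg])
  ss
}
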