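#' Extract the seed of a mature miRNA
#'
#' The seed is the principal target-recognition region of a miRNA: mature
#' positions 2-8 (1-based, inclusive), a 7-nt sequence.  Input is
#' normalized to the DNA alphabet (U -> T, uppercase).
#'
#' @param mature mature miRNA sequence(s), at least 8 nt.
#' @return Character vector of 7-nt seeds.
#' @examples
#' extractSeed("TGAGGTAGTAGGTTGTATAGTT")   # "GAGGTAG"
#' @export
extractSeed <- function(mature) {
  mature <- .norm_dna(mature)
  if (any(nchar(mature) < 8L))
    stop("mature sequence must be at least 8 nt to define a 7-nt seed")
  substr(mature, 2L, 8L)
}

#' Read a candidate miRNA gene table
#'
#' Reads a TSV with columns `gene_id`, `precursor`, `mature`, `star`,
#' `mature_count`, `star_count` (e.g. a summarized miRNA-prediction
#' output, or the simulator's `genes` truth table), normalizes sequences
#' to DNA, validates that mature and star are substrings of the
#' precursor, and adds the `seed` column.
#'
#' @param path TSV file path.
#' @return A validated data.frame with a `seed` column.
#' @export
readMirnaGenes <- function(path) {
  .stop_if_empty_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "precursor", "mature", "star", "mature_count",
            "star_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  validateMirnaGenes(df)
}

#' Validate (and normalize) a miRNA gene table
#'
#' @param genes data.frame with at least `gene_id`, `precursor`, `mature`,
#'   `star`, `mature_count`, `star_count`.
#' @return The normalized table with a `seed` column.
#' @export
validateMirnaGenes <- function(genes) {
  genes$precursor <- .norm_dna(genes$precursor)
  genes$mature <- .norm_dna(genes$mature)
  genes$star <- .norm_dna(genes$star)
  for (i in seq_len(nrow(genes))) {
    line <- paste0("gene table row ", i, " (", genes$gene_id[i], "): ")
    if (!grepl(genes$mature[i], genes$precursor[i], fixed = TRUE))
      stop(line, "mature is not a substring of the precursor")
    if (!grepl(genes$star[i], genes$precursor[i], fixed = TRUE))
      stop(line, "star is not a substring of the precursor")
  }
  if (any(genes$star_count < 0L)) stop("star_count must be >= 0")
  genes$seed <- extractSeed(genes$mature)
  genes
}

#' Star-coverage filter for novel miRNA candidates
#'
#' Discards novel candidates whose star (passenger strand) read support
#' is lower than `minStar` (default 5 reads; the bound is strict, so a
#' star count of exactly 5 is kept).  Genes already assigned to a known
#' family (non-NA `family` column) are never removed.
#'
#' @param genes miRNA gene data.frame with a `star_count` column and
#'   optionally a `family` column.
#' @param minStar minimum star read count (>= 0).
#' @return The filtered data.frame.
#' @export
starFilter <- function(genes, minStar = 5L) {
  if (minStar < 0L) stop("minStar must be >= 0")
  known <- if ("family" %in% names(genes)) !is.na(genes$family) else
    rep(FALSE, nrow(genes))
  keep <- known | genes$star_count >= minStar
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a reference pre-miRNA database FASTA
#'
#' Headers follow the `>id family=NAME mature=SEQ` convention; `family`
#' and `mature` attributes are required.  Sequences are normalized to
#' DNA and each entry's seed is derived from its mature annotation.
#'
#' @param path FASTA path.
#' @return A data.frame `id`, `family`, `precursor`, `mature`, `seed`.
#' @export
readMirnaReference <- function(path) {
  .stop_if_empty_file(path)
  ss <- Biostrings::readDNAStringSet(path)
  hd <- names(ss)
  id <- sub("\\s.*$", "", hd)
  fam <- ifelse(grepl("family=(\\S+)", hd),
                sub(".*family=(\\S+).*", "\\1", hd), NA_character_)
  mat <- ifelse(grepl("mature=(\\S+)", hd),
                sub(".*mature=(\\S+).*", "\\1", hd), NA_character_)
  if (anyNA(fam) || anyNA(mat))
    stop("reference headers must carry 'family=' and 'mature=' attributes")
  data.frame(id = id, family = fam,
             precursor = .norm_dna(as.character(ss)),
             mature = .norm_dna(mat),
             seed = extractSeed(.norm_dna(mat)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Local alignment with the package's fixed scoring: match +1, mismatch -2,
# linear gap -3.  Returns score, fractional identity (matches / alignment
# columns) and coverage of the shorter sequence.
.local_align <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 3)
  ncol_al <- nchar(as.character(Biostrings::alignedPattern(al)))
  ident <- if (ncol_al > 0) Biostrings::nmatch(al) / ncol_al else 0
  cov_a <- (BiocGenerics::end(al@pattern@range) -
              BiocGenerics::start(al@pattern@range) + 1) / nchar(a)
  cov_b <- (BiocGenerics::end(al@subject@range) -
              BiocGenerics::start(al@subject@range) + 1) / nchar(b)
  cov_short <- if (nchar(a) <= nchar(b)) cov_a else cov_b
  list(alignment = al, score = Biostrings::score(al), identity = ident,
       coverage = max(0, cov_short))
}

#' Assign miRNA genes to known families by best hit with identical seed
#'
#' Each gene's precursor is locally aligned (match +1, mismatch -2, gap
#' -3) against every reference precursor.  Hits must reach `minIdentity`
#' (fraction of matching alignment columns, default 0.6) over at least
#' `minCoverageFrac` (default 0.5) of the shorter sequence.  The best hit
#' is the highest-scoring passing hit (ties broken by identity, then
#' lexicographic reference id), and its family is assigned *only* when the
#' gene's seed is identical to the reference mature's seed; otherwise the
#' gene stays unassigned (novel candidate).
#'
#' @param genes miRNA gene data.frame (see [readMirnaGenes()]).
#' @param reference reference data.frame (see [readMirnaReference()]).
#' @param minIdentity,minCoverageFrac alignment acceptance thresholds.
#' @return `genes` with added columns `family` (NA when unassigned),
#'   `best_hit` (reference id) and `novel` (logical).
#' @export
assignKnownFamily <- function(genes, reference, minIdentity = 0.6,
                              minCoverageFrac = 0.5) {
  if (!"seed" %in% names(genes)) genes <- validateMirnaGenes(genes)
  genes$family <- NA_character_
  genes$best_hit <- NA_character_
  if (!nrow(genes)) { genes$novel <- logical(0); return(genes) }
  if (is.null(reference) || !nrow(reference)) {
    genes$novel <- TRUE
    return(genes)
  }
  ref <- reference[order(reference$id), , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    best <- NULL
    for (j in seq_len(nrow(ref))) {
      h <- .local_align(genes$precursor[i], ref$precursor[j])
      if (h$identity < minIdentity || h$coverage < minCoverageFrac) next
      if (is.null(best) || h$score > best$score ||
          (h$score == best$score && h$identity > best$identity)) {
        best <- h; best$j <- j
      }
    }
    if (!is.null(best)) {
      genes$best_hit[i] <- ref$id[best$j]
      if (identical(genes$seed[i], ref$seed[best$j]))
        genes$family[i] <- ref$family[best$j]
    }
  }
  genes$novel <- is.na(genes$family)
  genes
}

#' Cluster unassigned miRNA genes into novel families
#'
#' Builds an undirected graph over the genes with an edge when (a) the
#' local alignment of the two precursors passes the identity/coverage
#' thresholds (mutual hit; the scoring is symmetric) and (b) the seeds
#' differ by at most one substitution.  Novel families are the connected
#' components (single linkage), so a family may transitively contain seed
#' pairs at distance 2.  Family ids are deterministic: the
#' lexicographically smallest member gene id.
#'
#' @param genes data.frame of unassigned genes (with `seed`).
#' @param minIdentity,minCoverageFrac alignment thresholds, as in
#'   [assignKnownFamily()].
#' @return A data.frame `gene_id`, `family_id`, `seed`, sorted by family
#'   then gene id.
#' @export
clusterNovelFamilies <- function(genes, minIdentity = 0.6,
                                 minCoverageFrac = 0.5) {
  if (!"seed" %in% names(genes)) genes <- validateMirnaGenes(genes)
  n <- nrow(genes)
  if (!n) return(data.frame(gene_id = character(), family_id = character(),
                            seed = character(), stringsAsFactors = FALSE))
  ord <- order(genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1L) {
    edges <- integer(0)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (.seed_dist(genes$seed[i], genes$seed[j]) > 1L) next
        h <- .local_align(genes$precursor[i], genes$precursor[j])
        if (h$identity >= minIdentity && h$coverage >= minCoverageFrac)
          edges <- c(edges, i, j)
      }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)$membership
  fam <- vapply(seq_len(max(comp)), function(k)
    min(genes$gene_id[comp == k]), character(1))
  out <- data.frame(gene_id = genes$gene_id, family_id = fam[comp],
                    seed = genes$seed, stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.seed_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) return(nchar(a) + nchar(b))  # incomparable
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Check conservation of pre-miRNAs in a second genome
#'
#' A gene is flagged `shared` when a local alignment of its precursor
#' against the second genome (either strand) reaches `minIdentity`
#' (default 0.8) over at least `minCoverageFrac` (default 0.8) of the
#' precursor, *and* the alignment covers the seed region (precursor
#' positions of mature 2-8) without a single mismatch or indel — seed
#' conservation being the defining property of a family.
#'
#' @param genes miRNA gene data.frame (with `precursor`, `mature`).
#' @param secondGenome a `DNAStringSet` (or single sequence) of the other
#'   species' genome.
#' @param minIdentity,minCoverageFrac alignment thresholds.
#' @return A data.frame `gene_id`, `shared`; the number of shared genes is
#'   attached as `attr(, "n_shared")`.
#' @export
conservationCheck <- function(genes, secondGenome, minIdentity = 0.8,
                              minCoverageFrac = 0.8) {
  if (!"seed" %in% names(genes)) genes <- validateMirnaGenes(genes)
  if (is.character(secondGenome))
    secondGenome <- Biostrings::DNAStringSet(secondGenome)
  if (is(secondGenome, "DNAString"))
    secondGenome <- Biostrings::DNAStringSet(list(secondGenome))
  if (!length(secondGenome) || sum(BiocGenerics::width(secondGenome)) == 0)
    stop("second genome must be non-empty")
  shared <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    prec <- genes$precursor[i]
    mpos <- as.integer(regexpr(genes$mature[i], prec, fixed = TRUE))
    seed_rng <- c(mpos + 1L, mpos + 7L)   # precursor coords of mature 2..8
    for (ch in seq_along(secondGenome)) {
      for (subj in list(secondGenome[[ch]],
                        Biostrings::reverseComplement(secondGenome[[ch]]))) {
        h <- .local_align(prec, as.character(subj))
        if (h$identity < minIdentity || h$coverage < minCoverageFrac) next
        if (.seed_conserved(h$alignment, seed_rng)) { shared[i] <- TRUE; break }
      }
      if (shared[i]) break
    }
  }
  out <- data.frame(gene_id = genes$gene_id, shared = shared,
                    stringsAsFactors = FALSE)
  attr(out, "n_shared") <- sum(shared)
  out
}

# TRUE when pattern positions seed_rng[1]..seed_rng[2] are all aligned,
# gap-free and mismatch-free in a local pairwiseAlignment.
.seed_conserved <- function(al, seed_rng) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  pos <- BiocGenerics::start(al@pattern@range) - 1L
  for (col in seq_along(p)) {
    if (p[col] != "-") pos <- pos + 1L
    if (p[col] == "-") next
    if (pos >= seed_rng[1L] && pos <= seed_rng[2L]) {
      if (s[col] == "-" || p[col] != s[col]) return(FALSE)
    }
  }
  # every seed position must actually be inside the aligned pattern range
  BiocGenerics::start(al@pattern@range) <= seed_rng[1L] &&
    BiocGenerics::end(al@pattern@range) >= seed_rng[2L]
}
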