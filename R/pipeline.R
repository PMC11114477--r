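#' Default pipeline configuration
#'
#' Returns the full run configuration with every analysis parameter at
#' its standard default: overlap groups 4-20, 21-nt Dicer stratum,
#' Z-score threshold 1, pair filters (min coverage 5, |log2 ratio| <= 1.5,
#' miRNA-region exclusion), piRNA window 24-30 nt, star-coverage minimum
#' 5 reads, multimapper cap 100.  Pass overrides as a nested list to
#' [runPipeline()]; unknown keys are rejected.
#'
#' @return A named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "signature", "classify"),
    sim = list(),                      # SimConfig overrides
    input = list(sam = NULL, mirna_annotations = NULL, genes = NULL,
                 reference = NULL, genome2 = NULL, newick = NULL,
                 group_a = NULL, group_b = NULL),
    k_min = 4L, k_max = 20L,
    stratum = 21L,
    z_threshold = 1,
    min_coverage = 5L,
    max_abs_log_ratio = 1.5,
    sirna_window = c(21L, 21L),
    pirna_window = c(24L, 30L),
    min_star = 5L,
    max_hits = 100L,
    min_len = 18L, max_len = 35L
  )
}

.merge_config <- function(defaults, overrides) {
  if (is.null(overrides)) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]))
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]])
    else defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}

#' Run the small-RNA signature pipeline
#'
#' Orchestrates simulate -> read -> signature -> classify (-> mirna ->
#' tree) as a logged, reproducible run.  Every output, a YAML snapshot of
#' the effective configuration and a run log are written under `outdir`;
#' identical configurations produce identical outputs.  A stage failure
#' stops the run with an error naming the stage.
#'
#' @param config nested list of overrides of [defaultRunConfig()], or a
#'   path to a YAML file with the same structure.
#' @param outdir output directory (created; reused if existing).
#' @return Invisibly, a list with the stage results (`library`,
#'   `signature`, `pairs`, `profile`, `mirna`, `tree` as applicable) and
#'   `paths` of written files.
#' @examples
#' run <- runPipeline(list(sim = list(genomeLength = 30000, nMirnaReads = 50,
#'   nSirnaDuplexes = 100, nPirnaPairs = 100, nBackgroundReads = 500),
#'   seed = 11), outdir = tempfile())
#' run$signature
#' @export
runPipeline <- function(config = list(), outdir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .merge_config(defaultRunConfig(), config)
  if (missing(outdir) || is.null(outdir)) stop("outdir is required")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(line, log_con)
    message(line)
  }
  yaml::write_yaml(cfg, file.path(outdir, "config_snapshot.yaml"))
  results <- list(paths = c(config = file.path(outdir, "config_snapshot.yaml"),
                            log = log_path))
  stage <- function(name, expr) {
    logmsg("stage ", name, ": start")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- NULL
  lib <- NULL
  need_lib <- any(c("simulate", "signature", "classify") %in% cfg$stages)
  if ("simulate" %in% cfg$stages) {
    sim <- stage("simulate", {
      sc <- do.call(SimConfig, c(cfg$sim, list(seed = as.integer(cfg$seed))))
      s <- simulateLibrary(sc)
      writeGenomeAnnotation(s$genome, s$loci, outdir)
      writeLibrary(s$library, s$genome, outdir, truth = s$truth)
      if (!is.null(s$genes))
        utils::write.table(s$genes, file.path(outdir, "mirna_genes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      s
    })
    lib <- sim$library
    logmsg("simulated ", length(reads(lib)), " alignments (",
           totalMapped(lib), " read copies)")
  } else if (need_lib) {
    if (is.null(cfg$input$sam))
      stop("stage 'signature' needs input$sam when simulation is disabled")
    lib <- stage("read", readAlignments(cfg$input$sam, "sam"))
    logmsg("read ", length(reads(lib)), " alignments from ", cfg$input$sam)
  }
  if (!is.null(lib)) {
    lib <- collapseReads(lib)
    lib <- filterReads(lib, minLen = cfg$min_len, maxLen = cfg$max_len,
                       maxHits = cfg$max_hits)
    logmsg("after collapse + length/multimap filter: ", length(reads(lib)),
           " alignments retained (totalMapped ", totalMapped(lib), ")")
    results$library <- lib
  }

  mir_regions <- if (!is.null(sim))
    sim$loci[S4Vectors::mcols(sim$loci)$class == "mirna"]
  else if (!is.null(cfg$input$mirna_annotations))
    readAnnotations(cfg$input$mirna_annotations, "bed6")
  else GenomicRanges::GRanges()

  if ("signature" %in% cfg$stages) {
    results$signature <- stage("signature", {
      tab <- signatureTable(list(library = lib),
                            stratumLength = cfg$stratum,
                            kMin = cfg$k_min, kMax = cfg$k_max,
                            threshold = cfg$z_threshold,
                            file = file.path(outdir, "signature.tsv"))
      jsonlite::write_json(tab, file.path(outdir, "signature.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      tab
    })
    logmsg("signature: dicer ",
           ifelse(results$signature$dicer_present, "present", "absent"),
           " (z = ", signif(results$signature$dicer_z, 4), "), ping-pong ",
           ifelse(results$signature$pingpong_present, "present", "absent"),
           " (z = ", signif(results$signature$pingpong_z, 4), ")")
  }

  if ("classify" %in% cfg$stages) {
    results$pairs <- stage("classify", {
      cand <- rbind(
        findCandidatePairs(lib, "sirna", lengthWindow = cfg$sirna_window),
        findCandidatePairs(lib, "pirna", lengthWindow = cfg$pirna_window))
      flt <- filterPairs(cand, minCoverage = cfg$min_coverage,
                         maxAbsLogRatio = cfg$max_abs_log_ratio,
                         mirnaRegions = mir_regions)
      utils::write.table(flt, file.path(outdir, "pairs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      flt
    })
    for (cl in c("sirna", "pirna")) {
      sub <- results$pairs[results$pairs$class == cl, , drop = FALSE]
      logmsg(cl, " pairs: ", nrow(sub), " candidates, ",
             sum(sub$status == "kept"), " kept (",
             paste(vapply(c("low_coverage", "log_ratio", "mirna_region"),
                          function(r) paste0(r, "=", sum(sub$discard_reason == r)),
                          character(1)), collapse = ", "), ")")
    }
    results$profile <- classLengthProfile(lib, results$pairs, mir_regions)
    utils::write.table(results$profile, file.path(outdir, "class_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  genes <- if (!is.null(cfg$input$genes)) readMirnaGenes(cfg$input$genes)
  else if (!is.null(sim) && !is.null(sim$genes)) validateMirnaGenes(sim$genes)
  else NULL
  if ("mirna" %in% cfg$stages && !is.null(genes) &&
      !is.null(cfg$input$reference)) {
    results$mirna <- stage("mirna", {
      ref <- readMirnaReference(cfg$input$reference)
      asg <- assignKnownFamily(genes, ref)
      asg <- starFilter(asg, minStar = cfg$min_star)
      fam <- clusterNovelFamilies(asg[asg$novel, , drop = FALSE])
      utils::write.table(asg[, setdiff(names(asg), c("precursor"))],
                         file.path(outdir, "mirna_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fam, file.path(outdir, "mirna_novel_families.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out <- list(assignments = asg, novel_families = fam)
      if (!is.null(cfg$input$genome2)) {
        cons <- conservationCheck(
          asg[asg$novel, , drop = FALSE],
          Biostrings::readDNAStringSet(cfg$input$genome2))
        utils::write.table(cons, file.path(outdir, "mirna_conservation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$conservation <- cons
      }
      out
    })
    logmsg("mirna: ", sum(!results$mirna$assignments$novel), " known-family, ",
           length(unique(results$mirna$novel_families$family_id)),
           " novel families")
  }

  if ("tree" %in% cfg$stages && !is.null(cfg$input$newick)) {
    results$tree <- stage("tree", {
      tr <- parseNewickTree(cfg$input$newick, file = TRUE)
      ga <- readLines(cfg$input$group_a); gb <- readLines(cfg$input$group_b)
      cmp <- compareTipGroups(tr, ga[nzchar(ga)], gb[nzchar(gb)])
      utils::write.table(cmp$tips, file.path(outdir, "tree_distances.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cmp$summary, file.path(outdir, "tree_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cmp
    })
    logmsg("tree: U_A = ", results$tree$summary$u_a, ", p = ",
           signif(results$tree$summary$p_value, 4))
  }
  logmsg("run complete")
  invisible(results)
}
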