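## Evaluation: precision/recall against simulated truth, gene-run coverage,
## operon-pair support, conservation classes, leave-one-out stability and
## consensus annotation transfer.

#' Gene-pair precision and recall
#'
#' @param reconstructed,true character vectors of canonical NGP keys for
#'   one node.
#' @return list `precision` (`NA` when nothing was reconstructed) and
#'   `recall`.
#' @export
pairPrecisionRecall <- function(reconstructed, true) {
  inter <- length(intersect(reconstructed, true))
  list(precision = if (length(reconstructed)) inter / length(reconstructed) else NA_real_,
       recall = if (length(true)) inter / length(true) else NA_real_)
}

#' Gene-run coverage statistics of one node
#'
#' @param runset run set ([extractGeneRuns()]).
#' @param called_families families called present at the node.
#' @return list `n_runs`, `longest_run`, `genes_in_runs`, `pct` (coverage
#'   of the called gene set, in percent).
#' @export
coverageStats <- function(runset, called_families) {
  lens <- vapply(runset$runs, nrow, 1L)
  genes <- sum(lens)
  list(n_runs = length(runset$runs),
       longest_run = if (length(lens)) max(lens) else 0L,
       genes_in_runs = genes,
       pct = if (length(called_families)) 100 * genes / length(called_families) else 0)
}

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read an operon gene-pair table
#'
#' TSV with columns `genome_id`, `family_a`, `family_b` ("#" comments
#' allowed); pairs are direction-insensitive.
#'
#' @param path file path.
#' @return data.frame `genome_id, family_a, family_b`.
#' @export
readOperonPairs <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("genome_id", "family_a", "family_b")
  if (!all(need %in% names(d)))
    stop("operon table must have columns ", paste(need, collapse = ", "))
  d[need]
}

#' Operon support of a reconstructed gene run
#'
#' The fraction of the run's internal adjacent family pairs that are
#' known operon gene pairs; the run is supported when 60% or more are.
#'
#' @param run data.frame `family, strand` with at least 2 genes.
#' @param operon_pairs data.frame with `family_a`, `family_b` (any genome).
#' @param min_frac support threshold (default 0.6).
#' @return list `supported`, `fraction`, `n_pairs`.
#' @export
runOperonSupport <- function(run, operon_pairs, min_frac = 0.6) {
  if (nrow(run) < 2) stop("run must have at least 2 genes")
  keys <- .pairKey(run$family[-nrow(run)], run$family[-1])
  op <- unique(.pairKey(operon_pairs$family_a, operon_pairs$family_b))
  frac <- mean(keys %in% op)
  list(supported = frac >= min_frac, fraction = frac, n_pairs = length(keys))
}

#' Classify operon gene pairs by conservation
#'
#' Pairs are counted by the number of genomes they occur in: highly
#' conserved (HC) in 10 or more genomes, moderately conserved (MC) in 6
#' to 9, less conserved (LC) in 2 to 5; single-genome pairs are dropped.
#'
#' @param tables data.frame `genome_id, family_a, family_b`.
#' @return data.frame `family_a, family_b, n_genomes, class`.
#' @export
classifyOperonPairs <- function(tables) {
  key <- .pairKey(tables$family_a, tables$family_b)
  u <- unique(data.frame(genome_id = tables$genome_id, key = key,
                         stringsAsFactors = FALSE))
  cnt <- table(u$key)
  keys <- names(cnt)[cnt >= 2]
  n <- as.integer(cnt[keys])
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(family_a = vapply(parts, `[`, "", 1L),
             family_b = vapply(parts, `[`, "", 2L),
             n_genomes = n,
             class = ifelse(n >= 10, "HC", ifelse(n >= 6, "MC", "LC")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus functional annotation of a gene family
#'
#' @param annotations character vector of per-member annotations (`NA` or
#'   `""` = unannotated member).
#' @return list `annotation` (modal annotation, ties by lexicographic
#'   order; `"not annotated"` when no member is annotated), `consensus`
#'   (string `"k/n"` over annotated members).
#' @export
consensusAnnotation <- function(annotations) {
  ann <- annotations[!is.na(annotations) & nzchar(annotations)]
  if (length(ann) == 0)
    return(list(annotation = "not annotated", consensus = NA_character_))
  tab <- table(ann)
  best <- sort(names(tab)[tab == max(tab)])[1]
  list(annotation = best,
       consensus = sprintf("%d/%d", as.integer(tab[[best]]), length(ann)))
}

## recovery of one run in one replicate's run list
.runRecovered <- function(run, rep_runs, share_frac = 0.8) {
  n <- nrow(run)
  if (length(rep_runs) == 0) return(c(one = FALSE, two = FALSE))
  sh <- vapply(rep_runs, function(r) length(intersect(run$family, r$family)), 1L)
  sh <- sort(sh, decreasing = TRUE)
  c(one = sh[1] >= share_frac * n,
    two = sum(sh[seq_len(min(2, length(sh)))]) >= share_frac * n)
}

#' Leave-one-out stability of reconstructed gene runs
#'
#' For each genome, the reconstruction is rerun with that genome left out
#' (tree pruned of its leaf), and each focal-node gene run of at least
#' `min_run_length` genes from the full reconstruction is checked for
#' recovery: under the 1-fragment rule a replicate recovers a run if some
#' replicate run shares at least 80% of its genes; under the 2-fragment
#' rule the two largest-sharing replicate runs may cover the 80%
#' together. A run counts as recovered overall when at least
#' `ceil(recover_frac * n_replicates)` replicates recover it.
#'
#' @param genomes extant [GenomeSet-class].
#' @param tree [SpeciesTree-class].
#' @param focal_node node whose runs are tested; default the ingroup LCA
#'   (the root child with the most leaves).
#' @param leave_out genomes to drop one at a time; default all leaves of
#'   the focal clade.
#' @param min_run_length minimum run length examined (default 4).
#' @param share_frac sharing threshold (default 0.8).
#' @param recover_frac fraction of replicates required (default 0.818,
#'   i.e. 18 of 22).
#' @param ... passed to [runPipeline()].
#' @return list with `table` (per run: length, recovery counts, recovered
#'   flags under both rules) and `summary` (percent recovered).
#' @export
leaveOneOut <- function(genomes, tree, focal_node = NULL, leave_out = NULL,
                        min_run_length = 4, share_frac = 0.8,
                        recover_frac = 0.818, ...) {
  full <- runPipeline(genomes, tree, ...)
  if (is.null(focal_node)) {
    kids <- childIds(tree, rootId(tree))
    sizes <- vapply(kids, function(k) length(.leavesUnder(tree, k)), 1L)
    focal_node <- kids[which.max(sizes)]
  }
  focal_leaves <- .leavesUnder(tree, focal_node)
  if (is.null(leave_out)) leave_out <- focal_leaves
  runs <- Filter(function(r) nrow(r) >= min_run_length,
                 full@runs[[focal_node]]$runs)
  if (length(runs) == 0)
    return(list(table = data.frame(), summary = c(one = NA, two = NA)))
  hits1 <- matrix(FALSE, length(runs), length(leave_out))
  hits2 <- matrix(FALSE, length(runs), length(leave_out))
  for (j in seq_along(leave_out)) {
    dropped <- leave_out[j]
    ph <- ape::drop.tip(tree@phylo, dropped)
    if (ape::Ntip(ph) < 3) stop("protocol error: pruning leaves < 3 leaves")
    sub_tree <- speciesTree(ph)
    sub_gen <- subsetGenomes(genomes, setdiff(genomeIds(genomes), dropped))
    rep_state <- runPipeline(sub_gen, sub_tree, ...)
    target <- paste(setdiff(focal_leaves, dropped), collapse = "_")
    cand <- rep_state@runs[[target]]
    rep_runs <- if (is.null(cand)) list() else cand$runs
    for (i in seq_along(runs)) {
      rec <- .runRecovered(runs[[i]], rep_runs, share_frac)
      hits1[i, j] <- rec["one"]; hits2[i, j] <- rec["two"]
    }
  }
  need <- ceiling(recover_frac * length(leave_out))
  tab <- data.frame(run = seq_along(runs),
                    length = vapply(runs, nrow, 1L),
                    n_recovered_1 = rowSums(hits1),
                    n_recovered_2 = rowSums(hits2),
                    recovered_1 = rowSums(hits1) >= need,
                    recovered_2 = rowSums(hits2) >= need)
  list(table = tab,
       summary = c(one = 100 * mean(tab$recovered_1),
                   two = 100 * mean(tab$recovered_2)))
}

#' Precision/recall sweep over the gene-pair cutoff
#'
#' Replicates the cutoff calibration protocol on simulated data: for each
#' simulated dataset a single ML reconstruction of the character
#' posteriors is thresholded at every cutoff, and called NGP sets at
#' every internal node are scored against the simulated truth.
#'
#' @param sims list of [SimResult-class] objects.
#' @param cutoffs gene-pair cutoffs to sweep.
#' @param gene_occurrence_cutoff fixed family cutoff (default 0.9).
#' @param skip_singletons NGP extraction mode.
#' @return data.frame `cutoff, precision, recall` (means over nodes and
#'   datasets).
#' @export
sweepPairCutoffs <- function(sims, cutoffs = c(0.75, 0.8, 0.85, 0.9, 0.95, 0.97),
                             gene_occurrence_cutoff = 0.9,
                             skip_singletons = FALSE) {
  acc <- matrix(0, length(cutoffs), 3)   # precision sum, recall sum, n
  for (sim in sims) {
    tree <- sim@tree
    genomes <- simGenomeSet(sim, "leaves")
    gm <- geneContentMatrix(genomes)
    nm <- ngpMatrix(genomes, skip_singletons)
    gr <- fitRates(tree, gm)
    nr <- fitRates(tree, nm)
    gpost <- marginalPosteriors(tree, gm, gr$q01, gr$q10)
    npost <- marginalPosteriors(tree, nm, nr$q01, nr$q10)
    ends <- attr(nm, "ends")
    truth <- lapply(internalIds(tree), function(nd) simTruth(sim, nd))
    names(truth) <- internalIds(tree)
    for (ci in seq_along(cutoffs)) {
      called <- callPresence(gpost, npost, ends, "ml",
                             gene_occurrence_cutoff, cutoffs[ci])
      for (nd in internalIds(tree)) {
        pr <- pairPrecisionRecall(called[[nd]]$ngps$key, truth[[nd]]$ngps)
        if (!is.na(pr$precision)) {
          acc[ci, 1] <- acc[ci, 1] + pr$precision
          acc[ci, 2] <- acc[ci, 2] + pr$recall
          acc[ci, 3] <- acc[ci, 3] + 1
        }
      }
    }
  }
  data.frame(cutoff = cutoffs, precision = acc[, 1] / acc[, 3],
             recall = acc[, 2] / acc[, 3])
}
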