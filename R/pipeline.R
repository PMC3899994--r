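## End-to-end pipeline: characters -> ancestral states -> gene runs ->
## replicon architecture -> events, plus report writers.

#' Run the full ancestral reconstruction pipeline
#'
#' @param genomes extant [GenomeSet-class]; genome ids must match the
#'   tree leaves.
#' @param tree a [SpeciesTree-class].
#' @param method `"ml"` (default) or `"mp"`.
#' @param gene_occurrence_cutoff,gene_pair_cutoff ML presence cutoffs
#'   (default 0.9 each).
#' @param skip_singletons NGP extraction mode (default `FALSE`: strict
#'   physical adjacency).
#' @param min_run_len minimum reportable run length (default 2).
#' @param path_rule gene-run path selection rule (see
#'   [extractGeneRuns()]).
#' @param outgroup genome ids used as the root outgroup; default: the
#'   leaves of the smaller child clade of the root.
#' @param min_shared cross-link cutoff (default 1).
#' @param min_run_length_merge,low_floor replicon merge-signal parameters
#'   (defaults 4 and 0.1).
#' @param secondary_threshold secondary-chromosome core fraction
#'   (default 0.05).
#' @param seed integer seed covering every stochastic step (default 1).
#' @return a [ReconstructionState-class].
#' @export
runPipeline <- function(genomes, tree, method = c("ml", "mp"),
                        gene_occurrence_cutoff = 0.9, gene_pair_cutoff = 0.9,
                        skip_singletons = FALSE, min_run_len = 2,
                        path_rule = "longest", outgroup = NULL,
                        min_shared = 1, min_run_length_merge = 4,
                        low_floor = 0.1, secondary_threshold = 0.05,
                        seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  val <- validateInputs(tree, genomes)
  fatal <- grep("^fatal:", val$issues, value = TRUE)
  if (length(fatal)) stop("invalid inputs: ", paste(fatal, collapse = "; "))
  if (is.null(outgroup)) {
    kids <- childIds(tree, rootId(tree))
    sizes <- vapply(kids, function(k) length(.leavesUnder(tree, k)), 1L)
    outgroup <- .leavesUnder(tree, kids[which.min(sizes)])
  }
  gm <- geneContentMatrix(genomes)
  nm <- ngpMatrix(genomes, skip_singletons)
  ends <- attr(nm, "ends")
  if (method == "ml") {
    gr <- fitRates(tree, gm)
    nr <- if (nrow(nm)) fitRates(tree, nm) else gr
    gstates <- marginalPosteriors(tree, gm, gr$q01, gr$q10)
    nstates <- if (nrow(nm)) marginalPosteriors(tree, nm, nr$q01, nr$q10) else nm
    rates <- list(gene = gr, ngp = nr)
  } else {
    gstates <- mpReconstruct(tree, gm)$states
    nstates <- if (nrow(nm)) mpReconstruct(tree, nm)$states else nm
    rates <- NULL
  }
  called <- callPresence(gstates, nstates, ends, method,
                         gene_occurrence_cutoff, gene_pair_cutoff)
  genes <- lapply(called, `[[`, "genes")
  ngps <- lapply(called, `[[`, "ngps")
  runs <- lapply(internalIds(tree), function(nd)
    geneRunsForNode(genes[[nd]], ngps[[nd]], min_run_len, path_rule))
  names(runs) <- internalIds(tree)
  replicons <- reconstructArchitecture(
    tree, genes, runs, genomes, outgroup,
    min_shared = min_shared, min_run_length = min_run_length_merge,
    low_floor = low_floor, threshold = secondary_threshold, seed = seed)
  params <- list(method = method,
                 gene_occurrence_cutoff = gene_occurrence_cutoff,
                 gene_pair_cutoff = gene_pair_cutoff,
                 skip_singletons = skip_singletons, min_run_len = min_run_len,
                 path_rule = path_rule, outgroup = outgroup,
                 min_shared = min_shared,
                 min_run_length_merge = min_run_length_merge,
                 low_floor = low_floor,
                 secondary_threshold = secondary_threshold, seed = seed,
                 rates = rates)
  state <- new("ReconstructionState", tree = tree, method = method,
               params = params, genes = genes, ngps = ngps, runs = runs,
               replicons = replicons,
               events = data.frame())
  state@events <- inferEvents(state, genomes)
  state
}

#' Write reconstruction reports to a directory
#'
#' Emits the standard TSV reports: per-node presence calls, gene runs in
#' signed-family notation, replicon architecture with roles, per-branch
#' events, and the serialized parameter set.
#'
#' @param state a [ReconstructionState-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReconstructionReports <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- names(state@genes)
  pres <- do.call(rbind, lapply(nodes, function(nd) {
    g <- state@genes[[nd]]
    n <- state@ngps[[nd]]
    rbind(
      if (length(g)) data.frame(node_id = nd, character_key = g,
                                type = "family", score = NA_real_,
                                stringsAsFactors = FALSE),
      if (nrow(n)) data.frame(node_id = nd, character_key = n$key,
                              type = "ngp", score = n$score,
                              stringsAsFactors = FALSE))
  }))
  write.table(pres, file.path(dir, "presence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  runs <- do.call(rbind, lapply(nodes, function(nd) {
    rs <- state@runs[[nd]]$runs
    if (length(rs) == 0) return(NULL)
    data.frame(node_id = nd, run_index = seq_along(rs),
               length_in_genes = vapply(rs, nrow, 1L),
               total_weight = vapply(rs, function(r) attr(r, "weight"), 1),
               genes = vapply(rs, formatGeneRun, ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(runs)) runs <- data.frame(node_id = character())
  write.table(runs, file.path(dir, "gene_runs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  arch <- do.call(rbind, lapply(nodes, function(nd) {
    r <- state@replicons[[nd]]$roles
    if (is.null(r) || nrow(r) == 0) return(NULL)
    cbind(node_id = nd, r)
  }))
  write.table(arch, file.path(dir, "architecture.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(state@events, file.path(dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  p <- state@params
  p$rates <- NULL
  cfg <- vapply(names(p), function(k) paste0(k, "=", paste(p[[k]], collapse = ",")), "")
  writeLines(cfg, file.path(dir, "params.txt"))
  invisible(dir)
}
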