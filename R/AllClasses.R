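#' @import methods
#' @importFrom stats setNames optim kmeans sd median rexp rpois runif rgeom
#' @importFrom utils read.delim write.table head tail
NULL

setOldClass("phylo")

GENE_TABLE_COLUMNS <- c("genome_id", "replicon_id", "replicon_role", "circular",
                        "position", "strand", "family_id", "gene_id")

REPLICON_ROLES <- c("main_chromosome", "secondary_chromosome", "plasmid", "unknown")

#' Singleton family symbol
#'
#' Genes without a homolog in any other genome carry this family symbol.
#' They occupy positions on a replicon (and therefore interrupt gene runs)
#' but never form presence characters.
#' @export
SINGLETON <- "*"

#' GenomeSet: a collection of genomes as ordered, stranded gene strings
#'
#' Each genome is a set of replicons; each replicon an ordered string of
#' genes over the orthologous-family alphabet (plus the singleton symbol
#' `"*"`). The container enforces the input contract of the reconstruction:
#' positions within a replicon are a contiguous `1..n` sequence, no
#' non-singleton family occurs twice within one genome (no paralogs), and a
#' genome has at most one main chromosome.
#'
#' @slot genes data.frame with columns `genome_id`, `replicon_id`,
#'   `replicon_role`, `circular`, `position`, `strand`, `family_id`,
#'   `gene_id`, one row per gene.
#' @export
setClass("GenomeSet", representation(genes = "data.frame"))

setValidity("GenomeSet", function(object) {
  g <- object@genes
  msgs <- character()
  if (!all(GENE_TABLE_COLUMNS %in% names(g)))
    return(paste("missing columns:",
                 paste(setdiff(GENE_TABLE_COLUMNS, names(g)), collapse = ", ")))
  if (nrow(g) == 0) return(TRUE)
  if (!all(g$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (!all(g$replicon_role %in% REPLICON_ROLES))
    msgs <- c(msgs, "unknown replicon_role value")
  if (!is.logical(g$circular)) msgs <- c(msgs, "circular must be logical")
  ## positions contiguous per replicon
  key <- paste(g$genome_id, g$replicon_id, sep = "\r")
  for (k in unique(key)) {
    pos <- sort(g$position[key == k])
    if (!identical(as.integer(pos), seq_len(length(pos)))) {
      msgs <- c(msgs, sprintf("positions of replicon '%s' are not contiguous 1..n",
                              sub("\r", "/", k)))
      break
    }
  }
  ## no paralogs within a genome
  fam <- g[g$family_id != SINGLETON, c("genome_id", "family_id")]
  if (nrow(fam)) {
    dup <- duplicated(fam)
    if (any(dup)) {
      d <- fam[dup, ][1, ]
      msgs <- c(msgs, sprintf("paralog violation: family '%s' occurs more than once in genome '%s'",
                              d$family_id, d$genome_id))
    }
  }
  ## at most one main chromosome per genome
  mc <- unique(g[g$replicon_role == "main_chromosome", c("genome_id", "replicon_id")])
  if (nrow(mc) && any(table(mc$genome_id) > 1))
    msgs <- c(msgs, "a genome has more than one main_chromosome")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SpeciesTree: rooted bifurcating species tree bound to genome IDs
#'
#' Wraps an `ape` phylo object, validated to be rooted and strictly
#' bifurcating. Internal node identifiers are the underscore-join of the
#' descendant leaf labels in left-to-right order (e.g. the parent of
#' leaves `14` and `8` is `14_8`), so reconstruction reports can be traced
#' back to clades directly.
#'
#' @slot phylo an `ape::phylo` tree, rooted, binary, leaf labels = genome IDs.
#' @slot index internal navigation structure (parents, children, branch
#'   lengths, postorder, node labels) built once at construction.
#' @export
setClass("SpeciesTree", representation(phylo = "phylo", index = "list"))

setValidity("SpeciesTree", function(object) {
  ph <- object@phylo
  if (!ape::is.rooted(ph)) return("tree must be rooted")
  if (is.null(ph$tip.label) || any(!nzchar(ph$tip.label)))
    return("every leaf must be labeled")
  if (anyDuplicated(ph$tip.label)) return("duplicated leaf labels")
  tab <- tabulate(ph$edge[, 1])
  internal <- (ape::Ntip(ph) + 1):(ape::Ntip(ph) + ph$Nnode)
  if (any(tab[internal] != 2))
    return("unsupported topology: tree must be strictly bifurcating")
  TRUE
})

#' ReconstructionState: full per-node ancestral reconstruction
#'
#' Holds, for every internal node of the species tree, the called gene
#' (family) set, the called neighboring gene pairs with their scores, the
#' assembled gene runs, and the replicon assignment, plus the inferred
#' per-branch events.
#'
#' @slot tree the `SpeciesTree` used.
#' @slot method "mp" or "ml".
#' @slot params list of all reconstruction parameters (cutoffs, thresholds,
#'   seed) for provenance.
#' @slot genes named list: node id -> character vector of called families.
#' @slot ngps named list: node id -> data.frame of called NGPs
#'   (`key`, `fam1`, `end1`, `fam2`, `end2`, `score`).
#' @slot runs named list: node id -> run set (see [extractGeneRuns()]).
#' @slot replicons named list: node id -> replicon assignment (see
#'   [restoreChromosomes()]); leaves carry their observed assignment.
#' @slot events data.frame of per-branch events (see [inferEvents()]).
#' @export
setClass("ReconstructionState",
         representation(tree = "SpeciesTree", method = "character",
                        params = "list", genes = "list", ngps = "list",
                        runs = "list", replicons = "list",
                        events = "data.frame"))

#' SimResult: simulated tree, true genomes at every node, and event log
#'
#' Ground truth substrate for evaluating the reconstruction: the generated
#' species tree, the true genome at every node (ancestors included), and a
#' chronological event log whose replay from the root genome reproduces
#' every node genome exactly.
#'
#' @slot tree the generated `SpeciesTree`.
#' @slot genomes named list: node id -> genome (internal list form; use
#'   [simGenomeSet()] to obtain a `GenomeSet`).
#' @slot events data.frame event log (`branch`, `step`, `type`, and the
#'   concrete operands needed for deterministic replay).
#' @slot config the `simConfig()` list used.
#' @export
setClass("SimResult",
         representation(tree = "SpeciesTree", genomes = "list",
                        events = "data.frame", config = "list"))

setMethod("show", "GenomeSet", function(object) {
  g <- object@genes
  cat(sprintf("GenomeSet: %d genomes, %d genes, %d replicons\n",
              length(unique(g$genome_id)), nrow(g),
              nrow(unique(g[, c("genome_id", "replicon_id")]))))
  fams <- setdiff(unique(g$family_id), SINGLETON)
  cat(sprintf("  families: %d (plus %d singleton genes)\n",
              length(fams), sum(g$family_id == SINGLETON)))
})

setMethod("show", "SpeciesTree", function(object) {
  cat(sprintf("SpeciesTree: %d leaves, %d internal nodes, root '%s'\n",
              ape::Ntip(object@phylo), object@phylo$Nnode,
              rootId(object)))
})

setMethod("show", "ReconstructionState", function(object) {
  cat(sprintf("ReconstructionState (%s): %d ancestral nodes\n",
              object@method, length(object@genes)))
  cat(sprintf("  branches with events: %d\n",
              length(unique(object@events$child))))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d leaves, %d events logged\n",
              ape::Ntip(object@tree@phylo), nrow(object@events)))
})
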