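## Genome evolution simulator: generates a rooted bifurcating tree and
## evolves a start genome along it under gene-scale events (gain, loss,
## duplication, reversal, translocation, transposition) and replicon-scale
## events (gain, merge, split, loss). Every applied event is logged with
## its concrete operands, so replaying the log from the root genome
## reproduces every node genome exactly -- that replay is the ground-truth
## contract the evaluation relies on.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout: a start genome
#' with a 1,000-family main chromosome and a 200-family plasmid, evolved
#' into 21 extant genomes of which two form the outgroup clade.
#' Event rates are per unit branch length; branch lengths are drawn
#' i.i.d. uniform on `branch_range`.
#'
#' @param n_leaves total number of extant genomes (>= 3).
#' @param n_outgroup leaves placed in the outgroup clade attached at the
#'   root (>= 1).
#' @param root_chromosome,root_plasmid family counts of the start genome's
#'   replicons (`root_plasmid = 0` for a single-replicon start).
#' @param rates named list of per-event rates: `gene_gain`, `gene_loss`,
#'   `duplication`, `reversal`, `translocation`, `transposition`,
#'   `replicon_gain`, `replicon_merge`, `replicon_split`, `replicon_loss`.
#' @param branch_range range of the uniform branch-length distribution.
#' @param seg_p geometric length parameter for reversal/translocation/
#'   transposition segments (mean segment length `1/seg_p`).
#' @param duplicates_as_singletons emit duplicated copies with the
#'   singleton family symbol so simulated input honors the no-paralog
#'   contract (default `TRUE`).
#' @param seed integer seed.
#' @return config list.
#' @export
simConfig <- function(n_leaves = 21, n_outgroup = 2,
                      root_chromosome = 1000, root_plasmid = 200,
                      rates = list(), branch_range = c(0.05, 0.35),
                      seg_p = 0.25, duplicates_as_singletons = TRUE,
                      seed = 1L) {
  default_rates <- list(gene_gain = 60, gene_loss = 60, duplication = 20,
                        reversal = 40, translocation = 1, transposition = 8,
                        replicon_gain = 0.15, replicon_merge = 0.15,
                        replicon_split = 0.15, replicon_loss = 0.15)
  for (nm in names(rates)) {
    if (!nm %in% names(default_rates)) stop("unknown rate: ", nm)
    default_rates[[nm]] <- rates[[nm]]
  }
  if (any(unlist(default_rates) < 0)) stop("rates must be >= 0")
  if (n_leaves < 3) stop("need at least 3 leaves")
  list(n_leaves = n_leaves, n_outgroup = n_outgroup,
       root_chromosome = root_chromosome, root_plasmid = root_plasmid,
       rates = default_rates, branch_range = branch_range, seg_p = seg_p,
       duplicates_as_singletons = duplicates_as_singletons, seed = seed)
}

#' Generate a random rooted bifurcating tree
#'
#' Topology by uniform recursive splitting; the outgroup leaves form one
#' child clade of the root. Branch lengths are drawn i.i.d. from
#' `branch_gen`. Uses the current RNG state.
#'
#' @param n_leaves,n_outgroup leaf counts (see [simConfig()]).
#' @param branch_gen function(n) returning n branch lengths.
#' @return a [SpeciesTree-class]; ingroup leaves are labeled `g1..`,
#'   outgroup leaves `og1..`.
#' @export
generateTree <- function(n_leaves, n_outgroup = 2,
                         branch_gen = function(n) runif(n, 0.05, 0.25)) {
  build <- function(labels) {
    n <- length(labels)
    if (n == 1) return(labels)
    k <- if (n == 2) 1L else sample.int(n - 1, 1)
    left <- build(labels[seq_len(k)])
    right <- build(labels[(k + 1):n])
    sprintf("(%s:%.6f,%s:%.6f)", left, branch_gen(1), right, branch_gen(1))
  }
  ingroup <- paste0("g", seq_len(n_leaves - n_outgroup))
  outgroup <- paste0("og", seq_len(n_outgroup))
  ing <- build(sample(ingroup))
  outg <- if (n_outgroup == 1) outgroup else build(sample(outgroup))
  nwk <- sprintf("(%s:%.6f,%s:%.6f);", outg, branch_gen(1), ing, branch_gen(1))
  speciesTree(ape::read.tree(text = nwk))
}

## ---- event primitives -------------------------------------------------
## Each takes a genome (internal list form) and concrete operands and is
## used both when sampling events and when replaying a log.

.rootGenome <- function(config) {
  reps <- list()
  nc <- config$root_chromosome
  reps[["chr1"]] <- list(role = "main_chromosome", circular = FALSE,
                         family = paste0("f", seq_len(nc)),
                         strand = sample(c("+", "-"), nc, replace = TRUE))
  if (config$root_plasmid > 0) {
    np <- config$root_plasmid
    reps[["p1"]] <- list(role = "plasmid", circular = FALSE,
                         family = paste0("f", nc + seq_len(np)),
                         strand = sample(c("+", "-"), np, replace = TRUE))
  }
  list(genome_id = "root", replicons = reps)
}

.repliconSizes <- function(g) vapply(g$replicons, function(r) length(r$family), 1L)

.dropEmptyReplicons <- function(g) {
  g$replicons <- Filter(function(r) length(r$family) > 0, g$replicons)
  g
}

.ev_gene_gain <- function(g, rid, pos, family, strand) {
  r <- g$replicons[[rid]]
  n <- length(r$family)
  r$family <- append(r$family, family, after = pos - 1)
  r$strand <- append(r$strand, strand, after = pos - 1)
  g$replicons[[rid]] <- r
  g
}

.ev_gene_loss <- function(g, rid, pos) {
  r <- g$replicons[[rid]]
  r$family <- r$family[-pos]; r$strand <- r$strand[-pos]
  g$replicons[[rid]] <- r
  .dropEmptyReplicons(g)
}

.ev_reversal <- function(g, rid, pos, len) {
  r <- g$replicons[[rid]]
  sel <- pos:(pos + len - 1)
  r$family[sel] <- rev(r$family[sel])
  r$strand[sel] <- ifelse(rev(r$strand[sel]) == "+", "-", "+")
  g$replicons[[rid]] <- r
  g
}

.ev_move <- function(g, rid, pos, len, rid2, pos2) {
  ## cut [pos, pos+len-1] from rid and insert before position pos2 of rid2
  ## (pos2 refers to the destination after the cut when rid == rid2)
  r <- g$replicons[[rid]]
  sel <- pos:(pos + len - 1)
  fam <- r$family[sel]; str <- r$strand[sel]
  r$family <- r$family[-sel]; r$strand <- r$strand[-sel]
  g$replicons[[rid]] <- r
  r2 <- g$replicons[[rid2]]
  r2$family <- append(r2$family, fam, after = pos2 - 1)
  r2$strand <- append(r2$strand, str, after = pos2 - 1)
  g$replicons[[rid2]] <- r2
  .dropEmptyReplicons(g)
}

.ev_duplication <- function(g, rid, pos, rid2, pos2, family) {
  r <- g$replicons[[rid]]
  str <- r$strand[pos]
  .ev_gene_gain(g, rid2, pos2, family, str)
}

.ev_replicon_gain <- function(g, rid, pos, len, new_rid) {
  r <- g$replicons[[rid]]
  sel <- pos:(pos + len - 1)
  g$replicons[[new_rid]] <- list(role = "plasmid", circular = FALSE,
                                 family = r$family[sel], strand = r$strand[sel])
  r$family <- r$family[-sel]; r$strand <- r$strand[-sel]
  g$replicons[[rid]] <- r
  .dropEmptyReplicons(g)
}

.ev_replicon_merge <- function(g, rid1, rid2) {
  r1 <- g$replicons[[rid1]]; r2 <- g$replicons[[rid2]]
  r1$family <- c(r1$family, r2$family)
  r1$strand <- c(r1$strand, r2$strand)
  if (identical(r2$role, "main_chromosome")) r1$role <- "main_chromosome"
  g$replicons[[rid1]] <- r1
  g$replicons[[rid2]] <- NULL
  g
}

.ev_replicon_split <- function(g, rid, pos, new_rid) {
  ## cut after position pos; the tail becomes a new plasmid
  r <- g$replicons[[rid]]
  sel <- (pos + 1):length(r$family)
  g$replicons[[new_rid]] <- list(role = "plasmid", circular = FALSE,
                                 family = r$family[sel], strand = r$strand[sel])
  r$family <- r$family[-sel]; r$strand <- r$strand[-sel]
  g$replicons[[rid]] <- r
  g
}

.ev_replicon_loss <- function(g, rid) {
  g$replicons[[rid]] <- NULL
  g
}

## dispatch used by replay
.applyEvent <- function(g, ev) {
  switch(ev$type,
    gene_gain = .ev_gene_gain(g, ev$replicon, ev$pos, ev$family, ev$strand),
    gene_loss = .ev_gene_loss(g, ev$replicon, ev$pos),
    duplication = .ev_duplication(g, ev$replicon, ev$pos, ev$replicon2, ev$pos2,
                                  ev$family),
    reversal = .ev_reversal(g, ev$replicon, ev$pos, ev$len),
    translocation = .ev_move(g, ev$replicon, ev$pos, ev$len, ev$replicon2, ev$pos2),
    transposition = .ev_move(g, ev$replicon, ev$pos, ev$len, ev$replicon, ev$pos2),
    replicon_gain = .ev_replicon_gain(g, ev$replicon, ev$pos, ev$len, ev$replicon2),
    replicon_merge = .ev_replicon_merge(g, ev$replicon, ev$replicon2),
    replicon_split = .ev_replicon_split(g, ev$replicon, ev$pos, ev$replicon2),
    replicon_loss = .ev_replicon_loss(g, ev$replicon),
    stop("unknown event type: ", ev$type))
}

.emptyEventLog <- function() {
  data.frame(branch = character(), step = integer(), type = character(),
             replicon = character(), pos = integer(), len = integer(),
             replicon2 = character(), pos2 = integer(), family = character(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Evolve a genome along one branch
#'
#' Draws a Poisson(rate * t) count for every event type, applies the
#' events in shuffled order, and logs each applied event with the
#' concrete operands needed for deterministic replay. Events that are
#' inapplicable to the current genome (e.g. a replicon merge with a
#' single replicon) are skipped.
#'
#' @param genome genome in internal list form.
#' @param t branch length.
#' @param config a [simConfig()] list.
#' @param counter environment with `fam` (gained-family counter) and
#'   `rep` (new-replicon counter); created if missing.
#' @param forced_types character vector of event types applied (with
#'   sampled operands) before the stochastic events -- used to script
#'   specific scenarios such as a single replicon split on a chosen
#'   branch.
#' @return list(genome, events) where `events` is a data.frame of applied
#'   events (operands only; no `branch` column yet).
#' @export
evolveBranch <- function(genome, t, config, counter = NULL,
                         forced_types = character(0)) {
  if (is.null(counter)) {
    counter <- new.env()
    counter$fam <- 0L; counter$rep <- 0L
  }
  rates <- config$rates
  counts <- vapply(rates, function(r) rpois(1, r * t), 1L)
  sequence <- c(forced_types, sample(rep(names(counts), counts)))
  log <- list()
  g <- genome
  for (type in sequence) {
    sizes <- .repliconSizes(g)
    nrep <- length(sizes)
    if (nrep == 0) break
    rids <- names(sizes)
    ev <- NULL
    if (type == "gene_gain") {
      rid <- sample(rids, 1, prob = sizes + 1)
      counter$fam <- counter$fam + 1L
      ev <- list(type = type, replicon = rid,
                 pos = sample.int(sizes[[rid]] + 1L, 1),
                 family = paste0("n", counter$fam),
                 strand = sample(c("+", "-"), 1))
    } else if (type == "gene_loss") {
      rid <- sample(rids, 1, prob = sizes)
      ev <- list(type = type, replicon = rid, pos = sample.int(sizes[[rid]], 1))
    } else if (type == "duplication") {
      rid <- sample(rids, 1, prob = sizes)
      rid2 <- sample(rids, 1, prob = sizes + 1)
      counter$fam <- counter$fam + 1L
      fam <- if (config$duplicates_as_singletons) SINGLETON else
        g$replicons[[rid]]$family[sample.int(sizes[[rid]], 1)]
      ev <- list(type = type, replicon = rid, pos = sample.int(sizes[[rid]], 1),
                 replicon2 = rid2, pos2 = sample.int(sizes[[rid2]] + 1L, 1),
                 family = fam)
    } else if (type %in% c("reversal", "transposition", "translocation",
                           "replicon_gain")) {
      elig <- rids[sizes >= 2]
      if (type == "translocation" && nrep < 2) next
      if (length(elig) == 0) next
      rid <- sample(elig, 1, prob = sizes[elig])
      len <- min(1L + rgeom(1, config$seg_p), sizes[[rid]] - 1L)
      pos <- sample.int(sizes[[rid]] - len + 1L, 1)
      if (type == "reversal") {
        ev <- list(type = type, replicon = rid, pos = pos, len = len)
      } else if (type == "transposition") {
        rem <- sizes[[rid]] - len
        ev <- list(type = type, replicon = rid, pos = pos, len = len,
                   pos2 = sample.int(rem + 1L, 1))
      } else if (type == "translocation") {
        rid2 <- sample(setdiff(rids, rid), 1)
        ev <- list(type = type, replicon = rid, pos = pos, len = len,
                   replicon2 = rid2, pos2 = sample.int(sizes[[rid2]] + 1L, 1))
      } else {
        counter$rep <- counter$rep + 1L
        ev <- list(type = type, replicon = rid, pos = pos, len = len,
                   replicon2 = paste0("np", counter$rep))
      }
    } else if (type == "replicon_merge") {
      if (nrep < 2) next
      pair <- sample(rids, 2)
      ev <- list(type = type, replicon = pair[1], replicon2 = pair[2])
    } else if (type == "replicon_split") {
      elig <- rids[sizes >= 2]
      if (length(elig) == 0) next
      rid <- sample(elig, 1, prob = sizes[elig])
      counter$rep <- counter$rep + 1L
      ev <- list(type = type, replicon = rid,
                 pos = sample.int(sizes[[rid]] - 1L, 1),
                 replicon2 = paste0("np", counter$rep))
    } else if (type == "replicon_loss") {
      elig <- rids[vapply(g$replicons, function(r)
        !identical(r$role, "main_chromosome"), TRUE)]
      if (length(elig) == 0) next
      ev <- list(type = type, replicon = sample(elig, 1))
    }
    if (is.null(ev)) next
    g <- .applyEvent(g, ev)
    row <- .emptyEventLog()[1, ]
    for (nm in names(ev)) row[[nm]] <- ev[[nm]]
    row$step <- length(log) + 1L
    log[[length(log) + 1L]] <- row
  }
  events <- if (length(log)) do.call(rbind, log) else .emptyEventLog()
  rownames(events) <- NULL
  list(genome = g, events = events)
}

#' Replay a logged event sequence on a genome
#'
#' @param genome starting genome (internal list form).
#' @param events data.frame of events in log order (rows of the
#'   [evolveBranch()] / [simulateGenomes()] log, one branch).
#' @return the resulting genome.
#' @export
replayEvents <- function(genome, events) {
  g <- genome
  if (nrow(events)) for (k in seq_len(nrow(events)))
    g <- .applyEvent(g, as.list(events[k, ]))
  g
}

#' Simulate a full dataset: tree, genomes at every node, event log
#'
#' @param config a [simConfig()] list.
#' @param forced named list: child node id -> character vector of event
#'   types scripted on the branch above that node (see [evolveBranch()]).
#' @param tree optionally, a pre-generated [SpeciesTree-class] to evolve
#'   along (needed to name branches in `forced`); default: a fresh
#'   random tree.
#' @return a [SimResult-class].
#' @export
simulateGenomes <- function(config = simConfig(), forced = list(), tree = NULL) {
  set.seed(config$seed)
  if (is.null(tree))
    tree <- generateTree(config$n_leaves, config$n_outgroup,
                         function(n) runif(n, config$branch_range[1],
                                           config$branch_range[2]))
  root <- rootId(tree)
  genomes <- list()
  g0 <- .rootGenome(config)
  g0$genome_id <- root
  genomes[[root]] <- g0
  counter <- new.env(); counter$fam <- 0L; counter$rep <- 0L
  log <- list()
  ## preorder: parents before children
  for (v in rev(.internalPostorder(tree))) {
    for (child in childIds(tree, v)) {
      res <- evolveBranch(genomes[[v]], branchLengthOf(tree, child), config,
                          counter,
                          forced_types = if (child %in% names(forced))
                            forced[[child]] else character(0))
      res$genome$genome_id <- child
      genomes[[child]] <- res$genome
      if (nrow(res$events)) {
        res$events$branch <- child
        log[[length(log) + 1L]] <- res$events
      }
    }
  }
  events <- if (length(log)) do.call(rbind, log) else .emptyEventLog()
  rownames(events) <- NULL
  new("SimResult", tree = tree, genomes = genomes, events = events,
      config = config)
}

#' Extract simulated genomes as a GenomeSet
#'
#' @param sim a [SimResult-class].
#' @param nodes `"leaves"` (default), `"internal"`, `"all"`, or a
#'   character vector of node ids.
#' @return a [GenomeSet-class].
#' @export
simGenomeSet <- function(sim, nodes = "leaves") {
  ids <- if (identical(nodes, "leaves")) leafIds(sim@tree)
         else if (identical(nodes, "internal")) internalIds(sim@tree)
         else if (identical(nodes, "all")) nodeIds(sim@tree)
         else nodes
  .genomeSetFromList(sim@genomes[ids])
}

#' True NGP and family sets of a simulated node
#'
#' @param sim a [SimResult-class].
#' @param node node id.
#' @return list `families`, `ngps` (canonical keys), `assignment`
#'   (family -> replicon), `n_replicons`.
#' @export
simTruth <- function(sim, node) {
  g <- sim@genomes[[node]]
  fams <- character(0); reps <- character(0); keys <- character(0)
  for (rid in names(g$replicons)) {
    r <- g$replicons[[rid]]
    fb <- r$family != SINGLETON
    fams <- c(fams, r$family[fb])
    reps <- c(reps, rep(rid, sum(fb)))
    keys <- c(keys, .repliconNGPs(r$family, r$strand, r$circular))
  }
  list(families = sort(fams),
       ngps = sort(unique(keys)),
       assignment = data.frame(family = fams, replicon_id = reps,
                               stringsAsFactors = FALSE),
       n_replicons = length(g$replicons))
}
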