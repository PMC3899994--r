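## Branch-wise evolutionary event inference: gene flux, replicon-scale
## events from a shared-family bipartite mapping, reversals inside
## conserved gene runs, and per-run fates.

#' Gene gains and losses along a branch
#'
#' @param parent_set,child_set called family sets of parent and child.
#' @return list with `gains` and `losses` (character vectors).
#' @export
geneFlux <- function(parent_set, child_set) {
  list(gains = sort(setdiff(child_set, parent_set)),
       losses = sort(setdiff(parent_set, child_set)))
}

#' Replicon-scale events along a branch
#'
#' Parent and child replicons are mapped by shared family count (an edge
#' requires at least `max(3, 20%)` of the smaller replicon). A parent
#' mapped to two or more children is a split; two or more parents mapped
#' to one child a merge; an unmapped parent a replicon loss; an unmapped
#' child a replicon gain.
#'
#' @param parent_assign,child_assign assignment lists.
#' @param min_abs,min_frac mapping thresholds.
#' @return data.frame `type, parent_replicons, child_replicons`.
#' @export
mapReplicons <- function(parent_assign, child_assign, min_abs = 3, min_frac = 0.2) {
  pa <- parent_assign$assignment; ca <- child_assign$assignment
  preps <- sort(unique(pa$replicon_id)); creps <- sort(unique(ca$replicon_id))
  edges <- data.frame(p = character(), c = character(), stringsAsFactors = FALSE)
  for (p in preps) {
    pf <- pa$family[pa$replicon_id == p]
    for (cc in creps) {
      cf <- ca$family[ca$replicon_id == cc]
      s <- length(intersect(pf, cf))
      if (s >= max(min_abs, min_frac * min(length(pf), length(cf))))
        edges <- rbind(edges, data.frame(p = p, c = cc, stringsAsFactors = FALSE))
    }
  }
  ev <- data.frame(type = character(), parent_replicons = character(),
                   child_replicons = character(), stringsAsFactors = FALSE)
  add <- function(type, pr, cr) {
    ev <<- rbind(ev, data.frame(type = type,
                                parent_replicons = paste(pr, collapse = ","),
                                child_replicons = paste(cr, collapse = ","),
                                stringsAsFactors = FALSE))
  }
  for (p in preps) {
    mapped <- edges$c[edges$p == p]
    if (length(mapped) == 0) add("replicon_loss", p, character(0))
    else if (length(mapped) >= 2) add("replicon_split", p, mapped)
  }
  for (cc in creps) {
    mapped <- edges$p[edges$c == cc]
    if (length(mapped) == 0) add("replicon_gain", character(0), cc)
    else if (length(mapped) >= 2) add("replicon_merge", mapped, cc)
  }
  ev
}

## shared-gene best matching child run for a parent run
.runShares <- function(parent_run, child_runs) {
  vapply(child_runs, function(cr) length(intersect(parent_run$family, cr$family)), 1L)
}

#' Reversal detection within conserved gene runs
#'
#' For each parent run and the child run sharing at least two of its
#' genes, maximal blocks of consecutive shared genes whose order in the
#' child is exactly inverted and whose strands are all flipped are
#' reported as reversals.
#'
#' @param parent_runs,child_runs lists of runs (data.frame `family,
#'   strand`).
#' @return data.frame `parent_run, length, families`.
#' @export
detectReversals <- function(parent_runs, child_runs) {
  out <- data.frame(parent_run = integer(), length = integer(),
                    families = character(), stringsAsFactors = FALSE)
  for (i in seq_along(parent_runs)) {
    pr <- parent_runs[[i]]
    if (length(child_runs) == 0) next
    sh <- .runShares(pr, child_runs)
    if (max(sh) < 2) next
    cr <- child_runs[[which.max(sh)]]
    shared <- pr$family[pr$family %in% cr$family]
    if (length(shared) < 2) next
    ## runs have no intrinsic reading direction: orient the child run to
    ## agree with the parent (majority strand match over shared genes)
    ## before looking for inverted segments
    agree <- sum(pr$strand[match(shared, pr$family)] ==
                   cr$strand[match(shared, cr$family)])
    if (agree < length(shared) - agree) {
      cr <- data.frame(family = rev(cr$family),
                       strand = ifelse(rev(cr$strand) == "+", "-", "+"),
                       stringsAsFactors = FALSE)
    }
    ppos <- match(shared, pr$family)
    cpos <- match(shared, cr$family)
    pstr <- pr$strand[ppos]; cstr <- cr$strand[cpos]
    inverted <- pstr != cstr
    ## scan maximal blocks: consecutive in parent, strictly decreasing and
    ## consecutive in child, all strands flipped
    k <- 1
    while (k < length(shared)) {
      if (inverted[k] && inverted[k + 1] &&
          ppos[k + 1] == ppos[k] + 1 && cpos[k + 1] == cpos[k] - 1) {
        j <- k + 1
        while (j < length(shared) && inverted[j + 1] &&
               ppos[j + 1] == ppos[j] + 1 && cpos[j + 1] == cpos[j] - 1) j <- j + 1
        out <- rbind(out, data.frame(
          parent_run = i, length = j - k + 1,
          families = paste(shared[k:j], collapse = ","),
          stringsAsFactors = FALSE))
        k <- j + 1
      } else k <- k + 1
    }
  }
  out
}

#' Fate of a parent gene run in the child
#'
#' `conserved`: one child run shares at least 80% of the parent's genes
#' (`extended` if that child run is longer than the parent run);
#' `fragmented(k)`: the genes spread over k >= 2 child runs that together
#' cover at least 80%; otherwise `lost`.
#'
#' @param parent_run data.frame `family, strand`.
#' @param child_runs list of child runs.
#' @param share_frac recovery fraction (default 0.8).
#' @return list `status` in `{conserved, extended, fragmented, lost}` and
#'   `k` (number of fragments; `NA` unless fragmented).
#' @export
runFate <- function(parent_run, child_runs, share_frac = 0.8) {
  n <- nrow(parent_run)
  if (length(child_runs) == 0) return(list(status = "lost", k = NA_integer_))
  sh <- .runShares(parent_run, child_runs)
  best <- which.max(sh)
  if (sh[best] >= share_frac * n) {
    status <- if (nrow(child_runs[[best]]) > n) "extended" else "conserved"
    return(list(status = status, k = NA_integer_))
  }
  ord <- order(sh, decreasing = TRUE)
  covered <- character(0); k <- 0L
  for (j in ord) {
    if (sh[j] == 0) break
    covered <- union(covered, intersect(parent_run$family, child_runs[[j]]$family))
    k <- k + 1L
    if (length(covered) >= share_frac * n) return(list(status = "fragmented", k = k))
  }
  list(status = "lost", k = NA_integer_)
}

## observed singleton-free segments of a leaf genome, as run data.frames
.leafRuns <- function(genomes, genome_id, min_len = 2) {
  gl <- .genomeList(subsetGenomes(genomes, genome_id))[[genome_id]]
  runs <- list()
  for (rep in gl$replicons) {
    fb <- rep$family != SINGLETON
    r <- rle(fb)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < min_len) next
      sel <- idx_start[k]:idx_end[k]
      runs[[length(runs) + 1L]] <- data.frame(family = rep$family[sel],
                                              strand = rep$strand[sel],
                                              stringsAsFactors = FALSE)
    }
  }
  runs
}

#' Infer evolutionary events along every branch of a reconstruction
#'
#' Compares parent and child gene sets, replicon assignments and gene
#' runs along each tree edge. For leaf children the observed genome
#' (families, replicons, singleton-free segments) stands in for the
#' reconstruction.
#'
#' @param state a [ReconstructionState-class] (before event annotation) or
#'   the equivalent pieces; see [runPipeline()].
#' @param genomes the extant [GenomeSet-class].
#' @return data.frame `parent, child, type, detail, n` with one row per
#'   gene-flux summary, replicon event, reversal and run fate.
#' @export
inferEvents <- function(state, genomes) {
  tree <- state@tree
  rows <- list()
  emit <- function(parent, child, type, detail, n) {
    rows[[length(rows) + 1L]] <<- data.frame(parent = parent, child = child,
                                             type = type, detail = detail,
                                             n = n, stringsAsFactors = FALSE)
  }
  leafset <- leafIds(tree)
  getGenes <- function(id) {
    if (id %in% leafset)
      sort(unique(geneTable(genomes)$family_id[
        geneTable(genomes)$genome_id == id &
          geneTable(genomes)$family_id != SINGLETON]))
    else state@genes[[id]]
  }
  getRuns <- function(id) {
    if (id %in% leafset) .leafRuns(genomes, id) else state@runs[[id]]$runs
  }
  for (parent in internalIds(tree)) {
    for (child in childIds(tree, parent)) {
      pg <- getGenes(parent); cg <- getGenes(child)
      flux <- geneFlux(pg, cg)
      if (length(flux$gains))
        emit(parent, child, "gene_gain", paste(flux$gains, collapse = ","),
             length(flux$gains))
      if (length(flux$losses))
        emit(parent, child, "gene_loss", paste(flux$losses, collapse = ","),
             length(flux$losses))
      rev_ev <- mapReplicons(state@replicons[[parent]], state@replicons[[child]])
      if (nrow(rev_ev))
        for (k in seq_len(nrow(rev_ev)))
          emit(parent, child, rev_ev$type[k],
               paste(rev_ev$parent_replicons[k], rev_ev$child_replicons[k],
                     sep = "->"), 1L)
      prs <- getRuns(parent); crs <- getRuns(child)
      revs <- detectReversals(prs, crs)
      if (nrow(revs))
        for (k in seq_len(nrow(revs)))
          emit(parent, child, "reversal", revs$families[k], revs$length[k])
      for (i in seq_along(prs)) {
        fate <- runFate(prs[[i]], crs)
        emit(parent, child, "run_fate",
             sprintf("run%d:%s%s", i, fate$status,
                     if (!is.na(fate$k)) sprintf("(%d)", fate$k) else ""), 1L)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(parent = character(), child = character(), type = character(),
                  detail = character(), n = integer(), stringsAsFactors = FALSE)
}
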