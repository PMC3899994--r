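## Replicon architecture reconstruction.
##
## Bottom-up over the tree: the called families of an ancestral node are
## partitioned into co-inheritance groups by the (replicon in child 1,
## replicon in child 2) pattern of their descendants; a group graph links
## groups sharing a replicon slot; cross-links to the outgroup's group
## graph (the sibling node, or the designated outgroup genomes at the
## root) decide which groups merge back into one replicon. Because this
## criterion is stringent and tends to over-split, a second pass merges
## replicon pairs whose reconstructed gene runs straddle them, with a
## K-means separation of strong and weak merge proposals; finally core
## gene content distinguishes the main chromosome, secondary chromosomes
## and plasmids.

## An assignment is list(assignment = data.frame(family, replicon_id),
##                       roles = data.frame(replicon_id, role, ...)).

#' Co-inheritance groups of an ancestral node
#'
#' Families called present at the node are grouped by the identical pair
#' (replicon in child 1, replicon in child 2); families present in only
#' one child group by their single-slot pattern, and families present in
#' neither child are set aside as unplaced.
#'
#' @param families called families at the node.
#' @param assign1,assign2 the two children's assignments (data.frame
#'   `family`, `replicon_id`).
#' @return list with `groups` (data.frame `group_id, r1, r2, n`),
#'   `members` (named list group_id -> families) and `unplaced`.
#' @export
coInheritanceGroups <- function(families, assign1, assign2) {
  r1 <- assign1$replicon_id[match(families, assign1$family)]
  r2 <- assign2$replicon_id[match(families, assign2$family)]
  placed <- !(is.na(r1) & is.na(r2))
  unplaced <- families[!placed]
  fam <- families[placed]; r1 <- r1[placed]; r2 <- r2[placed]
  gid <- paste(ifelse(is.na(r1), "", r1), ifelse(is.na(r2), "", r2), sep = "|")
  members <- split(fam, gid)
  ids <- sort(names(members))
  members <- members[ids]
  parts <- strsplit(ids, "|", fixed = TRUE)
  groups <- data.frame(
    group_id = ids,
    r1 = vapply(parts, function(p) if (length(p) >= 1 && nzchar(p[1])) p[1] else NA_character_, ""),
    r2 = vapply(parts, function(p) if (length(p) >= 2 && nzchar(p[2])) p[2] else NA_character_, ""),
    n = vapply(members, length, 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(groups = groups, members = members, unplaced = unplaced)
}

#' Group graph: groups sharing a replicon slot
#'
#' Undirected edges between co-inheritance groups whose patterns share a
#' replicon in the same child slot.
#'
#' @param groups output of [coInheritanceGroups()].
#' @return list with `vertices` (group ids) and `edges` (data.frame `a, b`).
#' @export
buildGroupGraph <- function(groups) {
  g <- groups$groups
  n <- nrow(g)
  a <- character(0); b <- character(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      share <- (!is.na(g$r1[i]) && !is.na(g$r1[j]) && g$r1[i] == g$r1[j]) ||
               (!is.na(g$r2[i]) && !is.na(g$r2[j]) && g$r2[i] == g$r2[j])
      if (share) { a <- c(a, g$group_id[i]); b <- c(b, g$group_id[j]) }
    }
  }
  list(vertices = g$group_id,
       edges = data.frame(a = a, b = b, stringsAsFactors = FALSE),
       members = groups$members)
}

.graphComponents <- function(vertices, edges) {
  if (length(vertices) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = vertices))
  mem <- igraph::components(g)$membership
  unname(split(names(mem), mem))
}

#' Cross-link an ancestral group graph with its outgroup's
#'
#' Bipartite links between target and outgroup groups sharing at least
#' `min_shared` families.
#'
#' @param target_graph,outgroup_graph group graphs ([buildGroupGraph()]).
#' @param min_shared minimum shared family count (default 1; any shared
#'   ancestry links, placement is disambiguated downstream by the
#'   best-matching outgroup component).
#' @return data.frame `target, outgroup, shared`.
#' @export
crossLink <- function(target_graph, outgroup_graph, min_shared = 1) {
  out <- data.frame(target = character(), outgroup = character(),
                    shared = integer(), stringsAsFactors = FALSE)
  for (tg in target_graph$vertices) {
    tm <- target_graph$members[[tg]]
    for (og in outgroup_graph$vertices) {
      s <- length(intersect(tm, outgroup_graph$members[[og]]))
      if (s >= min_shared)
        out <- rbind(out, data.frame(target = tg, outgroup = og, shared = s,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

#' Assemble ancestral replicons from linked co-inheritance groups
#'
#' Every target group is attributed to the outgroup component it shares
#' the most families with (its best-matching component; ties resolve to
#' the lexicographically first component). Within each outgroup
#' component, the attributed target groups that are connected among
#' themselves (in the subgraph induced on them) merge into one replicon;
#' every unmerged group -- including groups with no outgroup link at all
#' -- forms its own replicon.
#'
#' @param target_graph the node's group graph.
#' @param links cross links ([crossLink()]).
#' @param outgroup_graph the outgroup's group graph.
#' @return assignment list (`assignment` data.frame family/replicon_id,
#'   `roles` with role `"unknown"`, replicon ids `R1..Rk` ordered by
#'   decreasing gene count).
#' @export
assembleReplicons <- function(target_graph, outgroup_graph, links) {
  verts <- target_graph$vertices
  if (length(verts) == 0)
    return(list(assignment = data.frame(family = character(),
                                        replicon_id = character(),
                                        stringsAsFactors = FALSE),
                roles = data.frame(replicon_id = character(), role = character(),
                                   stringsAsFactors = FALSE)))
  uf <- setNames(seq_along(verts), verts)
  findr <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  ocomp <- .graphComponents(outgroup_graph$vertices, outgroup_graph$edges)
  ## attribute each target group to its best-matching outgroup component
  comp_of <- character(0)
  for (k in seq_along(ocomp)) comp_of[ocomp[[k]]] <- k
  best <- list()
  if (nrow(links)) {
    links$comp <- comp_of[links$outgroup]
    for (tg in unique(links$target)) {
      l <- links[links$target == tg, , drop = FALSE]
      tot <- tapply(l$shared, l$comp, sum)
      best[[tg]] <- as.integer(names(tot)[order(-tot, names(tot))][1])
    }
  }
  for (k in seq_along(ocomp)) {
    linked <- names(best)[vapply(best, identical, TRUE, k)]
    if (length(linked) < 2) next
    ## connectivity within the subgraph induced on the linked groups
    e <- target_graph$edges
    e <- e[e$a %in% linked & e$b %in% linked, , drop = FALSE]
    for (cc in .graphComponents(linked, e)) {
      if (length(cc) < 2) next
      base <- findr(which(verts == cc[1]))
      for (other in cc[-1]) {
        r <- findr(which(verts == other))
        if (r != base) uf[r] <- base
      }
    }
  }
  cls <- vapply(seq_along(verts), findr, 1L)
  classes <- split(verts, cls)
  sizes <- vapply(classes, function(gs)
    sum(vapply(target_graph$members[gs], length, 1L)), 1L)
  classes <- classes[order(-sizes, vapply(classes, function(x) sort(x)[1], ""))]
  rows <- list()
  for (i in seq_along(classes)) {
    fams <- sort(unlist(target_graph$members[classes[[i]]], use.names = FALSE))
    rows[[i]] <- data.frame(family = fams, replicon_id = paste0("R", i),
                            stringsAsFactors = FALSE)
  }
  assignment <- do.call(rbind, rows)
  list(assignment = assignment,
       roles = data.frame(replicon_id = paste0("R", seq_along(classes)),
                          role = "unknown", stringsAsFactors = FALSE))
}

#' Attach unplaced families to replicons
#'
#' Families called present at a node but absent from both children carry
#' no co-inheritance pattern; they are attached to the majority replicon
#' of the gene run they sit on, falling back to the largest replicon.
#'
#' @param assign assignment list.
#' @param runset the node's run set ([extractGeneRuns()]).
#' @param unplaced families to place.
#' @export
placeUnassigned <- function(assign, runset, unplaced) {
  if (length(unplaced) == 0 || nrow(assign$assignment) == 0) return(assign)
  a <- assign$assignment
  largest <- names(sort(table(a$replicon_id), decreasing = TRUE))[1]
  place <- character(length(unplaced))
  for (i in seq_along(unplaced)) {
    f <- unplaced[i]
    tgt <- largest
    for (run in runset$runs) {
      if (f %in% run$family) {
        reps <- a$replicon_id[match(run$family, a$family)]
        reps <- reps[!is.na(reps)]
        if (length(reps)) tgt <- names(sort(table(reps), decreasing = TRUE))[1]
        break
      }
    }
    place[i] <- tgt
  }
  assign$assignment <- rbind(a, data.frame(family = unplaced, replicon_id = place,
                                           stringsAsFactors = FALSE))
  assign
}

#' Replicon merge signal of one gene run
#'
#' A run of at least `min_run_length` genes whose members map to two or
#' more replicons signals that those replicons may be over-split. For the
#' modal replicon (N1 genes) and each challenger (N2 genes) the relative
#' signal is N2/(N1+N2) (in (0, 0.5]); proposals below `low_floor` are
#' ignored; the absolute strength is the run length.
#'
#' @param run data.frame `family, strand`.
#' @param assign assignment list of the node.
#' @param min_run_length minimum run length to consider (default 4).
#' @param low_floor minimum relative signal (default 0.1).
#' @return data.frame `r1, r2, relative, absolute` (0 rows if none).
#' @export
runMergeSignal <- function(run, assign, min_run_length = 4, low_floor = 0.1) {
  none <- data.frame(r1 = character(), r2 = character(), relative = numeric(),
                     absolute = numeric(), stringsAsFactors = FALSE)
  if (nrow(run) < min_run_length) return(none)
  reps <- assign$assignment$replicon_id[match(run$family, assign$assignment$family)]
  reps <- reps[!is.na(reps)]
  tab <- sort(table(reps), decreasing = TRUE)
  if (length(tab) < 2) return(none)
  modal <- names(tab)[1]; n1 <- as.integer(tab[1])
  out <- none
  for (k in 2:length(tab)) {
    n2 <- as.integer(tab[k])
    rel <- n2 / (n1 + n2)
    if (rel < low_floor) next
    out <- rbind(out, data.frame(r1 = modal, r2 = names(tab)[k],
                                 relative = rel, absolute = nrow(run),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Cluster merge proposals into accepted and rejected sets
#'
#' Proposals pooled over all ancestral nodes are first aggregated per
#' (node, replicon pair): absolute strengths of runs supporting the same
#' pair are summed, the relative signal is the strongest observed. A
#' 2-means clustering on the standardized (absolute, relative) plane then
#' draws the line between accepting and rejecting; the cluster on the
#' high side (larger standardized centroid sum) is accepted.
#'
#' With a single proposal there is nothing to separate: it is accepted iff
#' it clears fixed floors (`relative >= 0.25` and `absolute >= 8`). With
#' no spread at all (all proposals identical) none is accepted.
#'
#' @param proposals data.frame `node, r1, r2, relative, absolute` (raw,
#'   per run).
#' @param seed integer seed for the K-means restarts.
#' @return aggregated data.frame with an `accepted` logical column.
#' @export
clusterProposals <- function(proposals, seed = 1L) {
  agg <- data.frame(node = character(), r1 = character(), r2 = character(),
                    relative = numeric(), absolute = numeric(),
                    accepted = logical(), stringsAsFactors = FALSE)
  if (is.null(proposals) || nrow(proposals) == 0) return(agg)
  key <- paste(proposals$node, pmin(proposals$r1, proposals$r2),
               pmax(proposals$r1, proposals$r2), sep = "\r")
  sp <- split(proposals, key)
  agg <- do.call(rbind, lapply(sp, function(d) data.frame(
    node = d$node[1], r1 = pmin(d$r1[1], d$r2[1]), r2 = pmax(d$r1[1], d$r2[1]),
    relative = max(d$relative), absolute = sum(d$absolute),
    stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg <- agg[order(agg$node, agg$r1, agg$r2), , drop = FALSE]
  n <- nrow(agg)
  if (n == 1) {
    agg$accepted <- agg$relative >= 0.25 & agg$absolute >= 8
    return(agg)
  }
  x <- cbind(agg$absolute, agg$relative)
  mu <- colMeans(x); s <- apply(x, 2, sd); s[s == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  ux <- unique(xs)
  if (nrow(ux) < 2) {              # no separation at all
    agg$accepted <- FALSE
    return(agg)
  }
  if (nrow(ux) == 2) {             # two distinct points: the split is forced
    cl <- apply(xs, 1, function(r) which(colSums(abs(t(ux) - r)) == 0)[1])
    centers <- ux
  } else {
    km <- local({ set.seed(seed); kmeans(xs, centers = 2, nstart = 10) })
    cl <- km$cluster; centers <- km$centers
  }
  hi <- which.max(rowSums(centers))
  agg$accepted <- cl == hi
  agg
}

#' Apply accepted merge proposals to a node's assignment
#'
#' Accepted replicon pairs are united transitively; the merged replicon
#' keeps the lexicographically smallest id of its members.
#'
#' @param assign assignment list.
#' @param accepted data.frame with columns `r1, r2` (already filtered to
#'   this node's accepted proposals).
#' @export
applyMerges <- function(assign, accepted) {
  if (is.null(accepted) || nrow(accepted) == 0) return(assign)
  reps <- sort(unique(c(assign$assignment$replicon_id, accepted$r1, accepted$r2)))
  uf <- setNames(seq_along(reps), reps)
  findr <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  for (k in seq_len(nrow(accepted))) {
    a <- findr(which(reps == accepted$r1[k]))
    b <- findr(which(reps == accepted$r2[k]))
    if (a != b) uf[max(a, b)] <- min(a, b)
  }
  newid <- vapply(assign$assignment$replicon_id,
                  function(r) reps[findr(which(reps == r))], "")
  assign$assignment$replicon_id <- unname(newid)
  assign$roles <- data.frame(replicon_id = sort(unique(newid)), role = "unknown",
                             stringsAsFactors = FALSE)
  assign
}

#' Distinguish chromosomes from plasmids by core gene content
#'
#' The replicon with the most core genes becomes the main chromosome
#' (ties: more genes overall, then lexicographic id); any other replicon
#' carrying at least `threshold` of the total core gene count becomes a
#' secondary chromosome; the rest are plasmids.
#'
#' @param assign assignment list.
#' @param core character vector of core families ([coreFamilies()]).
#' @param threshold fraction of total core genes required for a secondary
#'   chromosome (default 0.05).
#' @export
restoreChromosomes <- function(assign, core, threshold = 0.05) {
  a <- assign$assignment
  reps <- sort(unique(a$replicon_id))
  if (length(reps) == 0) return(assign)
  n_genes <- vapply(reps, function(r) sum(a$replicon_id == r), 1L)
  n_core <- vapply(reps, function(r) sum(a$family[a$replicon_id == r] %in% core), 1L)
  ord <- order(-n_core, -n_genes, reps)
  main <- reps[ord[1]]
  role <- ifelse(reps == main, "main_chromosome",
                 ifelse(n_core >= threshold * length(core) & length(core) > 0,
                        "secondary_chromosome", "plasmid"))
  assign$roles <- data.frame(replicon_id = reps, role = role,
                             n_genes = n_genes, n_core = n_core,
                             stringsAsFactors = FALSE, row.names = NULL)
  assign
}

## ---- orchestration over the tree -------------------------------------

## processing order: a node needs its own children and its sibling's
## children reconstructed; ordering internal nodes by
## max(height(v), height(sibling(v))) guarantees both.
.architectureOrder <- function(tree) {
  ix <- tree@index
  height <- integer(ix$ntot)
  for (v in ix$postorder)
    height[v] <- if (v <= ix$ntip) 0L else 1L + max(height[ix$children[[v]]])
  internal <- ix$internal
  key <- vapply(internal, function(v) {
    p <- ix$parent[v]
    if (is.na(p)) return(height[v] + 1L)   # root: strictly last among peers
    sib <- setdiff(ix$children[[p]], v)
    max(height[v], height[sib])
  }, 1L)
  ix$labels[internal[order(key, ix$labels[internal])]]
}

## group structure of a node acting as outgroup: internal node -> groups
## from its (already reconstructed) children; leaf -> one group per
## replicon; root outgroup -> pattern across the designated genomes.
.groupsOf <- function(node, tree, assignments, called) {
  kids <- childIds(tree, node)
  if (length(kids) == 0) {     # leaf
    a <- assignments[[node]]$assignment
    fams <- a$family
    gr <- coInheritanceGroups(fams, a, a[0, ])
  } else {
    gr <- coInheritanceGroups(called[[node]],
                              assignments[[kids[1]]]$assignment,
                              assignments[[kids[2]]]$assignment)
  }
  gr
}

#' Reconstruct the replicon architecture of every ancestral node
#'
#' Runs the full replicon pipeline: bottom-up group assembly with the
#' sibling node as outgroup (the designated outgroup genomes for the
#' root), attachment of pattern-less families, pooled K-means replicon
#' merge, and chromosome restoration.
#'
#' @param tree a [SpeciesTree-class].
#' @param called named list node id -> called families (internal nodes).
#' @param runsets named list node id -> run set.
#' @param genomes the extant [GenomeSet-class] (leaf assignments).
#' @param outgroup_ids genome ids used as the root's outgroup.
#' @param min_shared cross-link cutoff (default 1).
#' @param min_run_length,low_floor merge-signal parameters.
#' @param threshold secondary-chromosome core fraction (default 0.05).
#' @param seed seed for proposal clustering.
#' @return named list (leaves and internal nodes) of assignment lists with
#'   roles; internal nodes carry attribute `"merges"` describing accepted
#'   merges.
#' @export
reconstructArchitecture <- function(tree, called, runsets, genomes, outgroup_ids,
                                    min_shared = 1, min_run_length = 4,
                                    low_floor = 0.1, threshold = 0.05,
                                    seed = 1L) {
  if (length(outgroup_ids) == 0)
    stop("configuration error: no outgroup genomes designated for the root")
  assignments <- list()
  for (l in leafIds(tree)) assignments[[l]] <- .leafAssignment(genomes, l)
  core <- coreFamilies(genomes)
  order_ <- .architectureOrder(tree)
  unplaced_all <- list()
  for (v in order_) {
    kids <- childIds(tree, v)
    gr <- coInheritanceGroups(called[[v]],
                              assignments[[kids[1]]]$assignment,
                              assignments[[kids[2]]]$assignment)
    tg <- buildGroupGraph(gr)
    sib <- siblingId(tree, v)
    if (is.na(sib)) {           # root: designated outgroup genomes
      ogs <- outgroup_ids
      a1 <- assignments[[ogs[1]]]$assignment
      a2 <- if (length(ogs) >= 2) assignments[[ogs[2]]]$assignment else a1[0, ]
      fams <- unique(c(a1$family, a2$family))
      og_groups <- coInheritanceGroups(fams, a1, a2)
    } else {
      og_groups <- .groupsOf(sib, tree, assignments, called)
    }
    og <- buildGroupGraph(og_groups)
    links <- crossLink(tg, og, min_shared)
    asg <- assembleReplicons(tg, og, links)
    asg <- placeUnassigned(asg, runsets[[v]], gr$unplaced)
    assignments[[v]] <- asg
  }
  ## pooled gene-run merge signals, clustered once across all nodes
  props <- list()
  for (v in order_) {
    for (run in runsets[[v]]$runs) {
      p <- runMergeSignal(run, assignments[[v]], min_run_length, low_floor)
      if (nrow(p)) props[[length(props) + 1L]] <- cbind(node = v, p)
    }
  }
  props <- if (length(props)) do.call(rbind, props) else NULL
  decided <- clusterProposals(props, seed)
  for (v in order_) {
    acc <- decided[decided$accepted & decided$node == v, , drop = FALSE]
    assignments[[v]] <- applyMerges(assignments[[v]], acc)
    assignments[[v]] <- restoreChromosomes(assignments[[v]], core, threshold)
    attr(assignments[[v]], "merges") <- acc
  }
  attr(assignments, "proposals") <- decided
  assignments
}
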