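## Gene-run assembly from called NGPs.
##
## The called families and NGPs of an ancestral node define a weighted
## undirected graph on gene ends: every family contributes its head and
## tail node joined by an intra-gene edge of weight 1, and every called
## NGP contributes an inter-gene edge weighted by the reciprocal of its
## posterior (1 under MP). A minimum spanning forest (Kruskal, with
## deterministic tie-breaking on the canonical edge key) removes cycles;
## gene runs are then read off as legitimate paths -- paths whose intra-
## and inter-gene edges strictly alternate and that start and end with an
## intra-gene edge, so every reported gene carries its orientation.

#' Build the weighted gene-end adjacency graph of one ancestral node
#'
#' @param families character vector of called-present families.
#' @param ngps data.frame of called NGPs (`key, fam1, end1, fam2, end2,
#'   score`), consistent with `families`.
#' @return list with `nodes` (gene-end keys) and `edges`
#'   (data.frame `u, v, weight, type, key`).
#' @export
buildAdjacencyGraph <- function(families, ngps) {
  bad <- setdiff(c(ngps$fam1, ngps$fam2), families)
  if (length(bad))
    stop("NGP references uncalled family: ", paste(unique(bad), collapse = ", "))
  nodes <- c(geneEnd(families, "h"), geneEnd(families, "t"))
  intra <- data.frame(u = geneEnd(families, "h"), v = geneEnd(families, "t"),
                      weight = 1, type = "intra", stringsAsFactors = FALSE)
  if (nrow(ngps)) {
    ea <- geneEnd(ngps$fam1, ngps$end1)
    eb <- geneEnd(ngps$fam2, ngps$end2)
    inter <- data.frame(u = pmin(ea, eb), v = pmax(ea, eb),
                        weight = 1 / ngps$score, type = "inter",
                        stringsAsFactors = FALSE)
  } else {
    inter <- intra[0, ]
  }
  edges <- rbind(intra, inter)
  edges$key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), sep = "\r")
  edges <- edges[!duplicated(edges$key), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(nodes), edges = edges)
}

#' Minimum spanning forest (Kruskal)
#'
#' Per connected component, a minimum-weight spanning tree. Edges are
#' considered in order of (weight, canonical edge key), so ties resolve
#' deterministically to the lexicographically first edges.
#'
#' @param graph list as returned by [buildAdjacencyGraph()].
#' @return the same structure restricted to the forest edges.
#' @export
minimumSpanningForest <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) return(graph)
  id <- setNames(seq_along(graph$nodes), graph$nodes)
  parent <- seq_along(graph$nodes)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  keep <- logical(nrow(e))
  for (k in order(e$weight, e$key)) {
    ru <- find(id[[e$u[k]]]); rv <- find(id[[e$v[k]]])
    if (ru != rv) { parent[ru] <- rv; keep[k] <- TRUE }
  }
  out <- graph
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

## Gene-level view of a spanning forest: contract intra edges to "gene"
## vertices; each inter edge then records which end (port, "h"/"t") it
## touches on either gene. In a spanning tree of the end graph the gene
## view is again a tree.
.geneForest <- function(forest) {
  e <- forest$edges
  genes <- sort(unique(.parseEnd(forest$nodes)$family))
  inter <- e[e$type == "inter", , drop = FALSE]
  if (nrow(inter)) {
    pu <- .parseEnd(inter$u); pv <- .parseEnd(inter$v)
    edges <- data.frame(g1 = pu$family, p1 = pu$end,
                        g2 = pv$family, p2 = pv$end,
                        weight = inter$weight, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(g1 = character(), p1 = character(), g2 = character(),
                        p2 = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  list(genes = genes, edges = edges)
}

.otherPort <- function(p) ifelse(p == "h", "t", "h")

## adjacency list: per gene a data.frame(nbr, port, nport, weight),
## deterministically ordered
.geneAdjList <- function(gf) {
  adj <- setNames(vector("list", length(gf$genes)), gf$genes)
  empty <- data.frame(nbr = character(), port = character(), nport = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  for (g in gf$genes) adj[[g]] <- empty
  e <- gf$edges
  if (nrow(e)) {
    both <- rbind(
      data.frame(g = e$g1, nbr = e$g2, port = e$p1, nport = e$p2,
                 weight = e$weight, stringsAsFactors = FALSE),
      data.frame(g = e$g2, nbr = e$g1, port = e$p2, nport = e$p1,
                 weight = e$weight, stringsAsFactors = FALSE))
    both <- both[order(both$g, both$nbr, both$port), , drop = FALSE]
    for (g in unique(both$g)) adj[[g]] <- both[both$g == g, -1, drop = FALSE]
  }
  adj
}

## connected components of the gene tree restricted to `active` genes
.geneComponents <- function(adj, active) {
  comp <- list()
  seen <- setNames(rep(FALSE, length(active)), active)
  for (g0 in active) {
    if (seen[[g0]]) next
    queue <- g0; seen[[g0]] <- TRUE; members <- character(0)
    while (length(queue)) {
      g <- queue[1]; queue <- queue[-1]
      members <- c(members, g)
      nb <- adj[[g]]$nbr
      nb <- nb[nb %in% active]
      for (h in nb) if (!seen[[h]]) { seen[[h]] <- TRUE; queue <- c(queue, h) }
    }
    comp[[length(comp) + 1L]] <- sort(members)
  }
  comp
}

## Best legitimate path in one gene-tree component (genes `active`, all in
## one component). Returns list(genes, exit_ports, len, weight) or NULL.
## "longest": most genes, ties by lowest total weight (intra edges count 1
## each), deterministic traversal order breaks residual ties.
## "lowest-score": the legitimate path (>= 2 genes) with minimum weight.
.bestLegitimatePath <- function(adj, active, rule = c("longest", "lowest-score")) {
  rule <- match.arg(rule)
  if (length(active) == 0) return(NULL)
  if (rule == "lowest-score") {
    ## all edge weights are positive, so the minimum-weight legitimate
    ## path of >= 2 genes is always a single inter-gene edge: pick the
    ## cheapest one (ties by canonical gene pair)
    best <- NULL
    for (g in active) {
      rows <- adj[[g]]
      if (!nrow(rows)) next
      for (r in seq_len(nrow(rows))) {
        h <- rows$nbr[r]
        if (!h %in% active || h < g) next
        cand <- list(genes = c(g, h),
                     strand = c(if (rows$port[r] == "t") "+" else "-",
                                if (rows$nport[r] == "h") "+" else "-"),
                     len = 2L, weight = 2 + rows$weight[r])
        if (is.null(best) || cand$weight < best$weight ||
            (cand$weight == best$weight &&
               paste(cand$genes, collapse = "\r") <
                 paste(best$genes, collapse = "\r"))) best <- cand
      }
    }
    return(best)
  }
  inset <- setNames(rep(TRUE, length(active)), active)
  root <- active[1]
  ## iterative postorder on the rooted gene tree
  parent <- setNames(rep(NA_character_, length(active)), active)
  order_ <- character(0); stack <- root
  while (length(stack)) {
    g <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_ <- c(order_, g)
    nb <- adj[[g]]$nbr
    for (h in nb) {
      if (!isTRUE(inset[h]) || identical(h, parent[[g]])) next
      parent[[h]] <- g
      stack <- c(stack, h)
    }
  }
  order_ <- rev(order_)
  ## D[[g]][[port]]: best downward path starting at g, first inter edge via
  ## `port`; list(len, wt, edge = row index into adj[[g]] or NA)
  D <- list()
  better <- function(a, b) {  # is a better than b under the rule?
    if (rule == "longest") {
      if (a$len != b$len) return(a$len > b$len)
      a$wt < b$wt
    } else {
      a$wt < b$wt
    }
  }
  for (g in order_) {
    base <- list(len = 1L, wt = 1, edge = NA_integer_)
    Dg <- list(h = base, t = base)
    rows <- adj[[g]]
    if (nrow(rows)) for (r in seq_len(nrow(rows))) {
      h <- rows$nbr[r]
      if (!isTRUE(inset[h]) || !identical(parent[[h]], g)) next
      sub <- D[[h]][[.otherPort(rows$nport[r])]]
      cand <- list(len = 1L + sub$len, wt = 1 + rows$weight[r] + sub$wt,
                   edge = r)
      p <- rows$port[r]
      if (better(cand, Dg[[p]])) Dg[[p]] <- cand
    }
    D[[g]] <- Dg
  }
  ## apex combination
  bestApex <- NULL
  for (g in order_) {
    dh <- D[[g]]$h; dt <- D[[g]]$t
    cand <- list(len = dh$len + dt$len - 1L, wt = dh$wt + dt$wt - 1, apex = g)
    if (rule == "lowest-score" && cand$len < 2L) next
    if (is.null(bestApex) || better(cand, bestApex)) bestApex <- cand
  }
  if (is.null(bestApex)) return(NULL)
  apex <- bestApex$apex
  ## unfold one chosen downward branch into its directed edge list
  ## (from, fport, to, tport), walking away from the apex
  walk <- function(g, port) {
    edges <- list()
    repeat {
      d <- D[[g]][[port]]
      if (is.na(d$edge)) break
      r <- adj[[g]][d$edge, ]
      edges[[length(edges) + 1L]] <- list(from = g, fport = r$port,
                                          to = r$nbr, tport = r$nport)
      g <- r$nbr; port <- .otherPort(r$nport)
    }
    edges
  }
  le <- walk(apex, "h"); re <- walk(apex, "t")
  ## full traversal: reversed left branch, then right branch
  dir_edges <- c(
    rev(lapply(le, function(e) list(from = e$to, fport = e$tport,
                                    to = e$from, tport = e$fport))),
    re)
  if (length(dir_edges) == 0) {
    genes <- apex; strand <- "+"
  } else {
    genes <- c(vapply(dir_edges, `[[`, "", "from"),
               dir_edges[[length(dir_edges)]]$to)
    n <- length(genes)
    strand <- character(n)
    ## exiting via the tail end means the gene is traversed head->tail: "+"
    for (k in seq_len(n - 1))
      strand[k] <- if (dir_edges[[k]]$fport == "t") "+" else "-"
    strand[n] <- if (dir_edges[[n - 1]]$tport == "h") "+" else "-"
  }
  list(genes = genes, strand = strand, len = bestApex$len, weight = bestApex$wt)
}

#' Extract gene runs from a spanning forest
#'
#' Iteratively selects the best legitimate path of every tree fragment,
#' emits it as a stranded gene run, removes its genes, and recurses on the
#' resulting fragments until every fragment holds at most one gene.
#' Families never placed on a run (including families with no called NGP)
#' are reported as leftovers.
#'
#' @param forest output of [minimumSpanningForest()].
#' @param min_run_len minimum number of genes for a reportable run
#'   (default 2).
#' @param path_rule `"longest"` (default): most genes, ties by lowest
#'   total weight. `"lowest-score"`: the literal minimum-weight legitimate
#'   path of at least two genes.
#' @return list with `runs` (list of data.frame `family`, `strand`, with
#'   attributes `weight`) and `leftovers` (character vector of families).
#' @export
extractGeneRuns <- function(forest, min_run_len = 2, path_rule = "longest") {
  gf <- .geneForest(forest)
  adj <- .geneAdjList(gf)
  runs <- list()
  leftovers <- character(0)
  comps <- .geneComponents(adj, gf$genes)
  while (length(comps)) {
    comp <- comps[[1]]; comps <- comps[-1]
    if (length(comp) < 2 || length(comp) < min_run_len) {
      leftovers <- c(leftovers, comp)
      next
    }
    path <- .bestLegitimatePath(adj, comp, path_rule)
    if (is.null(path) || path$len < min_run_len) {
      leftovers <- c(leftovers, comp)
      next
    }
    run <- data.frame(family = path$genes, strand = path$strand,
                      stringsAsFactors = FALSE)
    attr(run, "weight") <- path$weight
    runs[[length(runs) + 1L]] <- run
    remaining <- setdiff(comp, path$genes)
    if (length(remaining))
      comps <- c(comps, .geneComponents(adj, remaining))
  }
  list(runs = runs, leftovers = sort(leftovers))
}

#' Assemble the gene runs of one ancestral node
#'
#' Convenience wrapper chaining [buildAdjacencyGraph()],
#' [minimumSpanningForest()] and [extractGeneRuns()].
#'
#' @inheritParams buildAdjacencyGraph
#' @inheritParams extractGeneRuns
#' @export
geneRunsForNode <- function(families, ngps, min_run_len = 2,
                            path_rule = "longest") {
  if (length(families) == 0)
    return(list(runs = list(), leftovers = character(0)))
  g <- buildAdjacencyGraph(families, ngps)
  extractGeneRuns(minimumSpanningForest(g), min_run_len, path_rule)
}

#' Format a gene run in signed-family notation
#'
#' @param run data.frame `family`, `strand`.
#' @return single string, e.g. `"+12_-7_+31"`.
#' @export
formatGeneRun <- function(run) {
  paste(paste0(ifelse(run$strand == "+", "+", "-"), run$family), collapse = "_")
}
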