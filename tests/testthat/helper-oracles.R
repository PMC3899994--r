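## Independent brute-force oracles used to validate the reconstruction
## machinery: full enumeration over internal state assignments (ML and MP)
## and over spanning trees (MST). Deliberately naive -- they share no code
## with the implementations they check.

## joint enumeration of the 2-state model: marginal posteriors + loglik
oracleML <- function(tree, x, q01, q10, eps = 1e-6) {
  ix <- tree@index
  P <- lapply(seq_len(ix$ntot), function(v) {
    if (is.na(ix$parent[v])) return(NULL)
    t <- ix$brlen[v]; if (is.na(t) || t <= 0) t <- eps
    transitionMatrix(q01, q10, t)
  })
  pi <- c(q10, q01) / (q01 + q10)
  internal <- ix$internal
  states <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  full <- integer(ix$ntot)
  for (l in seq_len(ix$ntip)) full[l] <- x[[ix$labels[l]]]
  joint <- numeric(nrow(states))
  for (s in seq_len(nrow(states))) {
    full[internal] <- states[s, ]
    p <- pi[full[ix$root] + 1]
    for (v in seq_len(ix$ntot)) if (!is.na(ix$parent[v]))
      p <- p * P[[v]][full[ix$parent[v]] + 1, full[v] + 1]
    joint[s] <- p
  }
  tot <- sum(joint)
  post <- vapply(seq_along(internal), function(j)
    sum(joint[states[, j] == 1]) / tot, 1)
  list(post = setNames(post, ix$labels[internal]), loglik = log(tot))
}

## exhaustive minimum change count over all internal labelings
oracleMP <- function(tree, x) {
  ix <- tree@index
  internal <- ix$internal
  states <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  full <- integer(ix$ntot)
  for (l in seq_len(ix$ntip)) full[l] <- x[[ix$labels[l]]]
  best <- Inf
  for (s in seq_len(nrow(states))) {
    full[internal] <- states[s, ]
    ch <- 0L
    for (v in seq_len(ix$ntot)) if (!is.na(ix$parent[v]))
      ch <- ch + (full[v] != full[ix$parent[v]])
    best <- min(best, ch)
  }
  best
}

## brute-force minimum spanning forest weight: per component, enumerate all
## (n-1)-edge subsets and keep the cheapest spanning one
oracleMSF <- function(graph) {
  e <- graph$edges
  adj_nodes <- function(edges) unique(c(edges$u, edges$v))
  comp_of <- local({
    ig <- igraph::graph_from_data_frame(e[, c("u", "v")], directed = FALSE,
                                        vertices = data.frame(name = graph$nodes))
    igraph::components(ig)$membership
  })
  total <- 0
  for (cid in unique(comp_of)) {
    nodes <- names(comp_of)[comp_of == cid]
    if (length(nodes) == 1) next
    ce <- e[e$u %in% nodes & e$v %in% nodes, , drop = FALSE]
    k <- length(nodes) - 1
    best <- Inf
    for (idx in utils::combn(nrow(ce), k, simplify = FALSE)) {
      sub <- ce[idx, , drop = FALSE]
      ig <- igraph::graph_from_data_frame(sub[, c("u", "v")], directed = FALSE,
                                          vertices = data.frame(name = nodes))
      if (igraph::components(ig)$no == 1) best <- min(best, sum(sub$weight))
    }
    total <- total + best
  }
  total
}

## enumerate every simple path of a tree-shaped end graph, filter for
## legitimacy (intra/inter alternation, intra terminal edges), and return
## the best by (gene count desc, weight asc)
oraclePath <- function(forest) {
  e <- forest$edges
  ig <- igraph::graph_from_data_frame(e[, c("u", "v")], directed = FALSE,
                                      vertices = data.frame(name = forest$nodes))
  etype <- setNames(e$type, paste(pmin(e$u, e$v), pmax(e$u, e$v)))
  ewt <- setNames(e$weight, paste(pmin(e$u, e$v), pmax(e$u, e$v)))
  best <- NULL
  vs <- forest$nodes
  for (i in seq_along(vs)) for (j in seq_along(vs)) {
    if (i == j) next
    sp <- suppressWarnings(
      igraph::shortest_paths(ig, vs[i], vs[j], weights = NA)$vpath[[1]])
    if (length(sp) < 2) next
    nm <- names(sp)
    keys <- paste(pmin(nm[-length(nm)], nm[-1]), pmax(nm[-length(nm)], nm[-1]))
    types <- etype[keys]
    if (types[1] != "intra" || types[length(types)] != "intra") next
    if (length(types) > 1 && any(types[-1] == types[-length(types)])) next
    genes <- sum(types == "intra")
    wt <- sum(ewt[keys])
    cand <- list(genes = genes, wt = wt)
    if (is.null(best) || cand$genes > best$genes ||
        (cand$genes == best$genes && cand$wt < best$wt - 1e-12)) best <- cand
  }
  best
}

## random tree with unit-free branch lengths and labeled tips
randomTree <- function(n, labels = paste0("t", seq_len(n))) {
  speciesTree(ape::rtree(n, tip.label = labels))
}

## random binary leaf matrix for one character
randomLeafStates <- function(tree) {
  setNames(sample(0:1, tree@index$ntip, replace = TRUE), leafIds(tree))
}

## one-character matrix helper
charMatrix <- function(x, name = "c1") {
  matrix(x, 1, dimnames = list(name, names(x)))
}
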