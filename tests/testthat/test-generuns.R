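test_that("adjacency graph has the specified nodes, edges and weights", {
  ngps <- ngpTable(c("1|t~2|h", "2|t~3|h"), score = c(0.95, 0.9))
  g <- buildAdjacencyGraph(c("1", "2", "3"), ngps)
  expect_length(g$nodes, 6)
  expect_equal(sum(g$edges$type == "intra"), 3)
  expect_equal(sum(g$edges$type == "inter"), 2)
  inter <- g$edges[g$edges$type == "inter", ]
  expect_setequal(round(inter$weight, 10), round(c(1 / 0.95, 1 / 0.9), 10))
  expect_true(all(g$edges$weight[g$edges$type == "intra"] == 1))
  ## no NGPs: perfect matching of intra edges
  g0 <- buildAdjacencyGraph(c("1", "2"), ngpTable(character(0)))
  expect_equal(nrow(g0$edges), 2)
  expect_error(buildAdjacencyGraph(c("1"), ngps), "uncalled")
})

test_that("Kruskal forest weight equals the brute-force minimum", {
  set.seed(12)
  for (rep in 1:40) {
    nfam <- sample(2:5, 1)      # up to 10 end-graph nodes
    fams <- as.character(seq_len(nfam))
    ends <- c(outer(fams, c("h", "t"), function(f, e) paste(f, e, sep = "|")))
    prs <- t(utils::combn(ends, 2))
    famof <- function(x) sub("[|].*", "", x)
    prs <- prs[famof(prs[, 1]) != famof(prs[, 2]), , drop = FALSE]
    sel <- sample(nrow(prs), min(nrow(prs), sample(2:6, 1)))
    keys <- apply(prs[sel, , drop = FALSE], 1, function(p)
      paste(sort(p), collapse = "~"))
    ngps <- ngpTable(unique(keys), score = runif(length(unique(keys)), 0.5, 1))
    g <- buildAdjacencyGraph(fams, ngps)
    msf <- minimumSpanningForest(g)
    expect_equal(sum(msf$edges$weight), oracleMSF(g), tolerance = 1e-9)
  }
})

test_that("spanning forest tie-breaking is deterministic and trees pass through", {
  ## equal-weight 4-cycle: the lexicographically first 3 edges survive
  edges <- data.frame(u = c("a", "b", "c", "a"), v = c("b", "c", "d", "d"),
                      weight = 1, type = "inter", stringsAsFactors = FALSE)
  edges$key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), sep = "\r")
  g <- list(nodes = c("a", "b", "c", "d"), edges = edges)
  msf <- minimumSpanningForest(g)
  expect_equal(sort(msf$edges$key),
               sort(edges$key[order(edges$key)][1:3]))
  ## tree-shaped input returned unchanged
  ngps <- ngpTable(c("1|t~2|h", "2|t~3|h"))
  gt <- buildAdjacencyGraph(c("1", "2", "3"), ngps)
  expect_equal(sort(minimumSpanningForest(gt)$edges$key), sort(gt$edges$key))
})

test_that("legitimate path selection agrees with exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:25) {
    nfam <- sample(3:6, 1)
    fams <- as.character(seq_len(nfam))
    ends <- c(outer(fams, c("h", "t"), function(f, e) paste(f, e, sep = "|")))
    prs <- t(utils::combn(ends, 2))
    famof <- function(x) sub("[|].*", "", x)
    prs <- prs[famof(prs[, 1]) != famof(prs[, 2]), , drop = FALSE]
    sel <- sample(nrow(prs), min(nrow(prs), nfam))
    keys <- unique(apply(prs[sel, , drop = FALSE], 1, function(p)
      paste(sort(p), collapse = "~")))
    g <- buildAdjacencyGraph(fams, ngpTable(keys, score = runif(length(keys), .5, 1)))
    msf <- minimumSpanningForest(g)
    want <- oraclePath(msf)
    got <- extractGeneRuns(msf)
    if (is.null(want) || want$genes < 2) {
      expect_length(got$runs, 0)
    } else {
      first <- got$runs[[1]]
      expect_equal(nrow(first), want$genes)
      expect_equal(attr(first, "weight"), want$wt, tolerance = 1e-9)
    }
  }
})

test_that("a star branch breaking alternation is excluded from the path", {
  ## chain 1-2-3 plus a second edge into gene 2's head: the extra branch
  ## cannot alternate and must not extend the selected path
  keys <- c("1|t~2|h", "2|t~3|h", "2|h~4|t")
  g <- buildAdjacencyGraph(c("1", "2", "3", "4"), ngpTable(keys))
  rs <- extractGeneRuns(minimumSpanningForest(g))
  expect_equal(nrow(rs$runs[[1]]), 3)
  expect_true(all(c(rs$runs[[1]]$family) %in% c("1", "2", "3")) ||
                all(c(rs$runs[[1]]$family) %in% c("4", "2", "3")))
})

test_that("equal-length candidate paths resolve to the lower weight", {
  ## gene 2 can extend left to 1 (weight 1/0.8) or to 4 (weight 1/0.99)
  keys <- c("1|t~2|h", "4|t~2|h", "2|t~3|h")
  g <- buildAdjacencyGraph(c("1", "2", "3", "4"),
                           ngpTable(keys, score = c(0.8, 0.99, 1)))
  rs <- extractGeneRuns(minimumSpanningForest(g))
  expect_equal(sort(rs$runs[[1]]$family), c("2", "3", "4"))
})

test_that("runs reproduce intact genomes and orientation is reconstructed", {
  set.seed(9)
  norm <- function(run) {
    fwd <- paste(paste0(run$strand, run$family), collapse = "_")
    bwd <- paste(paste0(ifelse(rev(run$strand) == "+", "-", "+"),
                        rev(run$family)), collapse = "_")
    min(fwd, bwd)
  }
  for (rep in 1:10) {
    signed <- paste0(sample(c("+", "-"), 12, replace = TRUE), 1:12)
    signed[sample(12, 2)] <- "*"   # singletons split the string into runs
    gs <- GenomeSet(repliconRows("A", "r1", signed))
    keys <- genomeNGPs(gs, "A")
    fams <- setdiff(sub("^[+-]", "", signed), "*")
    rs <- geneRunsForNode(fams, ngpTable(keys))
    got <- sort(vapply(rs$runs, norm, ""))
    want <- sort(vapply(AncestralGenomes:::.leafRuns(gs, "A"), norm, ""))
    expect_equal(got, want)
  }
})

test_that("every called family lands in exactly one run or in leftovers", {
  set.seed(14)
  sim <- simulateGenomes(simConfig(n_leaves = 6, n_outgroup = 2,
                                   root_chromosome = 40, root_plasmid = 10,
                                   seed = 31))
  gen <- simGenomeSet(sim, "leaves")
  st <- runPipeline(gen, sim@tree, method = "mp", seed = 1)
  for (nd in internalIds(sim@tree)) {
    rs <- st@runs[[nd]]
    placed <- c(unlist(lapply(rs$runs, function(r) r$family)), rs$leftovers)
    expect_setequal(placed, st@genes[[nd]])
    expect_equal(anyDuplicated(placed), 0)
    for (r in rs$runs) expect_equal(anyDuplicated(r$family), 0)
  }
})

test_that("a parent run whose child lost interior NGPs splits into fragments", {
  ## parent chain 1..6; child evidence lacks the 3-4 adjacency
  keys <- c("1|t~2|h", "2|t~3|h", "4|t~5|h", "5|t~6|h")
  rs <- geneRunsForNode(as.character(1:6), ngpTable(keys))
  expect_length(rs$runs, 2)
  expect_setequal(vapply(rs$runs, nrow, 1L), c(3L, 3L))
  ## empty graph
  rs0 <- geneRunsForNode(character(0), ngpTable(character(0)))
  expect_length(rs0$runs, 0)
})

test_that("run extraction is invariant under whole-genome strand flips", {
  signed <- c("+1", "-2", "+3", "+4", "-5")
  flip <- ifelse(grepl("^-", rev(signed)), sub("^-", "+", rev(signed)),
                 sub("^[+]", "-", rev(signed)))
  norm <- function(run) {
    fwd <- paste(paste0(run$strand, run$family), collapse = "_")
    bwd <- paste(paste0(ifelse(rev(run$strand) == "+", "-", "+"),
                        rev(run$family)), collapse = "_")
    min(fwd, bwd)
  }
  runsOf <- function(sgn) {
    gs <- GenomeSet(repliconRows("A", "r1", sgn))
    rs <- geneRunsForNode(as.character(1:5), ngpTable(genomeNGPs(gs, "A")))
    sort(vapply(rs$runs, norm, ""))
  }
  expect_equal(runsOf(signed), runsOf(flip))
})

test_that("the literal lowest-score path rule remains available", {
  keys <- c("1|t~2|h", "2|t~3|h")
  rs <- geneRunsForNode(as.character(1:3), ngpTable(keys, score = c(1, 0.5)),
                        path_rule = "lowest-score")
  ## lowest-score legitimate path of >= 2 genes is the 1-2 pair
  expect_equal(sort(rs$runs[[1]]$family), c("1", "2"))
})
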