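test_that("zero rates leave every node genome identical to the root", {
  sim <- simulateGenomes(simConfig(n_leaves = 6, n_outgroup = 2,
                                   root_chromosome = 20, root_plasmid = 5,
                                   rates = zeroRates, seed = 3))
  expect_equal(nrow(sim@events), 0)
  root <- sim@genomes[[rootId(sim@tree)]]$replicons
  for (nd in nodeIds(sim@tree))
    expect_identical(sim@genomes[[nd]]$replicons, root)
})

test_that("replaying the event log reproduces every node genome exactly", {
  sim <- simulateGenomes(simConfig(n_leaves = 8, n_outgroup = 2,
                                   root_chromosome = 60, root_plasmid = 15,
                                   seed = 42))
  expect_gt(nrow(sim@events), 0)
  for (v in internalIds(sim@tree)) {
    for (ch in childIds(sim@tree, v)) {
      got <- replayEvents(sim@genomes[[v]],
                          sim@events[sim@events$branch == ch, , drop = FALSE])
      got$genome_id <- sim@genomes[[ch]]$genome_id
      expect_identical(got, sim@genomes[[ch]], label = ch)
    }
  }
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulateGenomes(simConfig(n_leaves = 6, root_chromosome = 30,
                                  root_plasmid = 8, seed = 99))
  s2 <- simulateGenomes(simConfig(n_leaves = 6, root_chromosome = 30,
                                  root_plasmid = 8, seed = 99))
  expect_identical(s1@genomes, s2@genomes)
  expect_identical(s1@events, s2@events)
  expect_identical(ape::write.tree(s1@tree@phylo), ape::write.tree(s2@tree@phylo))
})

test_that("generated trees have the requested leaves and binary topology", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    tr <- generateTree(n, n_outgroup = min(2, n - 1))
    expect_equal(ape::Ntip(tr@phylo), n)
    expect_equal(length(internalIds(tr)), n - 1)
  }
})

test_that("default configuration matches the study conditions", {
  cfg <- simConfig()
  expect_equal(cfg$n_leaves, 21)
  expect_equal(cfg$n_outgroup, 2)
  sim <- simulateGenomes(simConfig(rates = zeroRates, seed = 2))
  expect_equal(ape::Ntip(sim@tree@phylo), 21)
  root <- sim@genomes[[rootId(sim@tree)]]
  expect_equal(length(root$replicons), 2)
  expect_equal(sum(vapply(root$replicons, function(r) length(r$family), 1L)), 1200)
  roles <- vapply(root$replicons, function(r) r$role, "")
  expect_setequal(unname(roles), c("main_chromosome", "plasmid"))
})

test_that("leaf families stay within root plus gained families", {
  sim <- simulateGenomes(simConfig(n_leaves = 7, n_outgroup = 2,
                                   root_chromosome = 40, root_plasmid = 10,
                                   seed = 8))
  rootfam <- unlist(lapply(sim@genomes[[rootId(sim@tree)]]$replicons,
                           function(r) r$family))
  gained <- sim@events$family[sim@events$type == "gene_gain"]
  for (l in leafIds(sim@tree)) {
    fams <- setdiff(unlist(lapply(sim@genomes[[l]]$replicons,
                                  function(r) r$family)), SINGLETON)
    expect_true(all(fams %in% c(rootfam, gained)))
  }
})

test_that("zero replicon-event rates keep the root's replicon count everywhere", {
  sim <- simulateGenomes(simConfig(n_leaves = 8, n_outgroup = 2,
                                   root_chromosome = 50, root_plasmid = 12,
                                   rates = geneRatesOnly(), seed = 13))
  for (nd in nodeIds(sim@tree))
    expect_equal(length(sim@genomes[[nd]]$replicons), 2, label = nd)
})

test_that("forced event types are applied on the requested branch", {
  cfg <- simConfig(n_leaves = 6, n_outgroup = 2, root_chromosome = 30,
                   root_plasmid = 8, rates = zeroRates, seed = 6)
  set.seed(cfg$seed)
  tree <- generateTree(cfg$n_leaves, cfg$n_outgroup,
                       function(n) runif(n, cfg$branch_range[1],
                                         cfg$branch_range[2]))
  target <- setdiff(internalIds(tree), rootId(tree))[1]
  sim <- simulateGenomes(cfg, forced = setNames(list("replicon_split"), target),
                         tree = tree)
  ev <- sim@events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "replicon_split")
  expect_equal(ev$branch, target)
  expect_equal(length(sim@genomes[[target]]$replicons), 3)
})

test_that("gene-count drift matches the gain-loss rate difference in expectation", {
  ## net drift over one branch: (gain - loss) * t; Monte-Carlo over many
  ## replicate branches from a fixed genome
  cfg <- simConfig(n_leaves = 3, root_chromosome = 300, root_plasmid = 0,
                   rates = list(gene_gain = 30, gene_loss = 10,
                                duplication = 0, reversal = 0,
                                translocation = 0, transposition = 0,
                                replicon_gain = 0, replicon_merge = 0,
                                replicon_split = 0, replicon_loss = 0),
                   seed = 1)
  set.seed(9)
  g0 <- AncestralGenomes:::.rootGenome(cfg)
  t <- 0.5
  drift <- replicate(200, {
    g1 <- evolveBranch(g0, t, cfg)$genome
    sum(vapply(g1$replicons, function(r) length(r$family), 1L)) - 300
  })
  expect_equal(mean(drift), (30 - 10) * t, tolerance = 0.05 * (30 + 10) * t)
})
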