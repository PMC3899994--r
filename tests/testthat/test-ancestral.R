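test_that("Fitch reconstruction matches definitional cases", {
  tr <- speciesTree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  ## both children present -> node present
  m <- charMatrix(c(A = 1, B = 1, C = 1, D = 1))
  r <- mpReconstruct(tr, m)
  expect_true(all(r$states == 1))
  expect_equal(unname(r$changes), 0L)
  ## present in one leaf of a balanced quartet -> absent at all ancestors
  m2 <- charMatrix(c(A = 1, B = 0, C = 0, D = 0))
  r2 <- mpReconstruct(tr, m2)
  expect_true(all(r2$states == 0))
  expect_equal(unname(r2$changes), 1L)
})

test_that("Fitch change counts equal the exhaustive minimum on random trees", {
  set.seed(101)
  for (rep in 1:60) {
    tr <- randomTree(sample(3:6, 1))
    x <- randomLeafStates(tr)
    r <- mpReconstruct(tr, charMatrix(x))
    expect_equal(unname(r$changes), oracleMP(tr, x),
                 info = ape::write.tree(tr@phylo))
  }
})

test_that("pruning likelihood matches closed forms and enumeration", {
  q01 <- 0.3; q10 <- 0.7
  pi1 <- q01 / (q01 + q10)
  ## two-leaf closed form: sum over root states of pi_r P(r->s1) P(r->s2)
  tr2 <- speciesTree(ape::read.tree(text = "(A:0.4,B:1.3);"))
  for (s in list(c(A = 1, B = 1), c(A = 1, B = 0), c(A = 0, B = 0))) {
    P1 <- transitionMatrix(q01, q10, 0.4); P2 <- transitionMatrix(q01, q10, 1.3)
    hand <- log(sum(c(1 - pi1, pi1) *
                      P1[, s[["A"]] + 1] * P2[, s[["B"]] + 1]))
    expect_equal(unname(pruneLikelihood(tr2, charMatrix(s), q01, q10)), hand,
                 tolerance = 1e-12)
  }
  ## 4-leaf enumeration oracle
  set.seed(5)
  tr4 <- randomTree(4)
  x <- randomLeafStates(tr4)
  bf <- oracleML(tr4, x, q01, q10)
  expect_equal(unname(pruneLikelihood(tr4, charMatrix(x), q01, q10)),
               bf$loglik, tolerance = 1e-10)
})

test_that("marginal posteriors match enumeration on random trees", {
  set.seed(33)
  for (rep in 1:40) {
    tr <- randomTree(sample(3:6, 1))   # up to 5 internal nodes
    x <- randomLeafStates(tr)
    q01 <- runif(1, 0.05, 2); q10 <- runif(1, 0.05, 2)
    bf <- oracleML(tr, x, q01, q10)
    post <- marginalPosteriors(tr, charMatrix(x), q01, q10)
    expect_lt(max(abs(post[1, names(bf$post)] - bf$post)), 1e-8)
  }
})

test_that("posteriors hit the all-present limit and are child-order invariant", {
  tr <- speciesTree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  m <- charMatrix(c(A = 1, B = 1, C = 1))
  post <- marginalPosteriors(tr, m, q01 = 0.5, q10 = 1e-6)
  expect_true(all(post > 0.999))
  tr_swap <- speciesTree(ape::read.tree(text = "(C:2,(B:1,A:1):1);"))
  post2 <- marginalPosteriors(tr_swap, m, q01 = 0.4, q10 = 0.6)
  post1 <- marginalPosteriors(tr, m, q01 = 0.4, q10 = 0.6)
  expect_equal(post1[1, "A_B_C"], post2[1, "C_B_A"], tolerance = 1e-12)
})

test_that("rate fitting recovers simulated rates and respects symmetry", {
  simChars <- function(tree, n, q01, q10) {
    ix <- tree@index
    P <- lapply(seq_len(ix$ntot), function(v)
      if (!is.na(ix$parent[v])) transitionMatrix(q01, q10, ix$brlen[v]))
    m <- matrix(0L, n, ix$ntip,
                dimnames = list(paste0("c", 1:n), ix$labels[seq_len(ix$ntip)]))
    for (k in seq_len(n)) {
      st <- integer(ix$ntot)
      st[ix$root] <- rbinom(1, 1, q01 / (q01 + q10))
      for (v in rev(ix$postorder)) if (!is.na(ix$parent[v]))
        st[v] <- rbinom(1, 1, P[[v]][st[ix$parent[v]] + 1, 2])
      m[k, ] <- st[seq_len(ix$ntip)]
    }
    m
  }
  set.seed(2)
  tr <- randomTree(20)
  m <- simChars(tr, 500, q01 = 0.4, q10 = 0.9)
  f <- fitRates(tr, m)
  expect_lt(abs(f$q01 - 0.4) / 0.4, 0.5)
  expect_lt(abs(f$q10 - 0.9) / 0.9, 0.5)
  ## label swap (0 <-> 1) swaps the fitted rates
  f2 <- fitRates(tr, 1L - m)
  expect_equal(f2$q01, f$q10, tolerance = 0.02)
  expect_equal(f2$q10, f$q01, tolerance = 0.02)
  ## constant characters: boundary minimum-rate model with a warning
  mc <- matrix(1L, 3, tr@index$ntip,
               dimnames = list(paste0("k", 1:3), leafIds(tr)))
  expect_warning(fc <- fitRates(tr, mc), "constant")
  expect_lt(fc$q10, 1e-5)
})

test_that("presence calls respect cutoffs, boundaries and consistency", {
  nodes <- c("n1")
  gs <- matrix(c(0.95, 0.95, 0.89), 3, 1,
               dimnames = list(c("1", "2", "3"), nodes))
  keys <- c("1|t~2|h", "2|t~3|h")
  ns <- matrix(c(0.9, 0.95), 2, 1, dimnames = list(keys, nodes))
  ends <- AncestralGenomes:::.parseNGP(keys)
  called <- callPresence(gs, ns, ends, "ml")
  ## 0.89 < 0.9 -> family 3 absent; posterior exactly at cutoff -> present
  expect_setequal(called$n1$genes, c("1", "2"))
  expect_equal(called$n1$ngps$key, "1|t~2|h")
  ## the 2~3 pair was called but dropped because family 3 is absent
  expect_equal(called$n1$dropped_ngps, "2|t~3|h")
})

test_that("raising the gene pair cutoff never enlarges the called NGP set", {
  sim <- simulateGenomes(simConfig(n_leaves = 8, n_outgroup = 2,
                                   root_chromosome = 40, root_plasmid = 10,
                                   seed = 17))
  gen <- simGenomeSet(sim, "leaves")
  nm <- ngpMatrix(gen)
  gm <- geneContentMatrix(gen)
  fr <- fitRates(sim@tree, nm)
  np <- marginalPosteriors(sim@tree, nm, fr$q01, fr$q10)
  fg <- fitRates(sim@tree, gm)
  gp <- marginalPosteriors(sim@tree, gm, fg$q01, fg$q10)
  ends <- attr(nm, "ends")
  prev <- NULL
  for (cut in c(0.75, 0.85, 0.95)) {
    called <- callPresence(gp, np, ends, "ml", gene_pair_cutoff = cut)
    sets <- lapply(called, function(x) x$ngps$key)
    if (!is.null(prev))
      for (nd in names(sets)) expect_true(all(sets[[nd]] %in% prev[[nd]]))
    prev <- sets
  }
})
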