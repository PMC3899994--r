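asg <- function(family, replicon) {
  data.frame(family = family, replicon_id = replicon, stringsAsFactors = FALSE)
}

test_that("co-inheritance groups partition families by replicon pattern", {
  ## two-chromosome/plasmid children with one family moved: patterns
  ## (C,C), (P,P), (C,P) and two single-slot loss patterns
  a1 <- asg(c("a", "b", "c", "d", "e", "x"), c("C", "C", "C", "P", "P", "C"))
  a2 <- asg(c("a", "b", "c", "d", "e", "y"), c("C", "C", "P", "P", "P", "C"))
  gr <- coInheritanceGroups(c("a", "b", "c", "d", "e", "x", "y", "z"), a1, a2)
  expect_equal(nrow(gr$groups), 5)
  expect_setequal(gr$groups$group_id, c("C|C", "C|P", "P|P", "C|", "|C"))
  expect_equal(gr$unplaced, "z")
  expect_setequal(gr$members[["C|C"]], c("a", "b"))
  ## identical children with 2 replicons -> exactly 2 groups
  gr2 <- coInheritanceGroups(c("a", "b", "d"), a1[1:4, ], a1[1:4, ])
  expect_equal(nrow(gr2$groups), 2)
})

test_that("group graph links groups sharing a replicon slot", {
  a1 <- asg(c("a", "b", "c"), c("C", "P1", "P1"))
  a2 <- asg(c("a", "b", "c"), c("C", "C", "P2"))
  gr <- coInheritanceGroups(c("a", "b", "c"), a1, a2)
  gg <- buildGroupGraph(gr)
  ## (C,C)-(P1,C) share C in child 2; (P1,C)-(P1,P2) share P1 in child 1
  expect_equal(nrow(gg$edges), 2)
  has <- function(x, y) any((gg$edges$a == x & gg$edges$b == y) |
                              (gg$edges$a == y & gg$edges$b == x))
  expect_true(has("C|C", "P1|C"))
  expect_true(has("P1|C", "P1|P2"))
  expect_false(has("C|C", "P1|P2"))
})

test_that("cross links respect the shared-gene cutoff boundary", {
  tg <- buildGroupGraph(coInheritanceGroups(
    c("a", "b", "c"), asg(c("a", "b", "c"), "C"), asg(c("a", "b", "c"), "C")))
  og <- buildGroupGraph(coInheritanceGroups(
    c("a", "b", "z"), asg(c("a", "b", "z"), "X"), asg(c("a", "b", "z"), "X")))
  expect_equal(nrow(crossLink(tg, og, min_shared = 2)), 1)   # shares a,b
  expect_equal(crossLink(tg, og, min_shared = 2)$shared, 2)  # at the cutoff
  expect_equal(nrow(crossLink(tg, og, min_shared = 3)), 0)
  og0 <- buildGroupGraph(coInheritanceGroups(
    c("q", "r", "s"), asg(c("q", "r", "s"), "X"), asg(c("q", "r", "s"), "X")))
  expect_equal(nrow(crossLink(tg, og0)), 0)                  # no shared genes
})

test_that("replicon assembly merges linked groups per outgroup component", {
  ## worked four-species configuration: ancestral node under study has
  ## groups (C,C), (P1,C), (P1,P2), (P2,-); the outgroup ancestor has a
  ## chromosome group and a plasmid group. Groups linked to the outgroup
  ## chromosome that are connected merge into the ancestral chromosome;
  ## the unlinked (P2,-) group stays its own replicon.
  fams <- c(paste0("c", 1:6), paste0("m", 1:4), paste0("p", 1:4), paste0("q", 1:3))
  a1 <- asg(fams, c(rep("C", 6), rep("P1", 4), rep("P1", 4), rep("P2", 3)))
  a2 <- asg(fams[1:14], c(rep("C", 6), rep("C", 4), rep("P2", 4)))
  gr <- coInheritanceGroups(fams, a1, a2)
  tg <- buildGroupGraph(gr)
  og1 <- asg(fams[1:10], rep("Co", 10))      # outgroup: c*, m* on chromosome
  og2 <- asg(c(fams[1:10], fams[11:14]), c(rep("Co", 10), rep("Po", 4)))
  ogr <- buildGroupGraph(coInheritanceGroups(fams[1:14], og1, og2))
  links <- crossLink(tg, ogr)
  out <- assembleReplicons(tg, ogr, links)
  reps <- split(out$assignment$family, out$assignment$replicon_id)
  ## (C,C) and (P1,C) merged (both best-match the outgroup chromosome
  ## component and share slot C); (P1,P2) and (P2,-) separate
  merged <- reps[[which(vapply(reps, function(r) "c1" %in% r, TRUE))]]
  expect_setequal(merged, c(paste0("c", 1:6), paste0("m", 1:4)))
  expect_length(reps, 3)
  ## all groups mutually linked and connected -> a single replicon
  tg2 <- buildGroupGraph(coInheritanceGroups(
    c("a", "b", "c", "d"), asg(c("a", "b", "c", "d"), c("C", "C", "P", "P")),
    asg(c("a", "b", "c", "d"), c("C", "P", "P", "P"))))
  og3 <- buildGroupGraph(coInheritanceGroups(
    c("a", "b", "c", "d"), asg(c("a", "b", "c", "d"), "X"),
    asg(c("a", "b", "c", "d"), "X")))
  out2 <- assembleReplicons(tg2, og3, crossLink(tg2, og3))
  expect_equal(length(unique(out2$assignment$replicon_id)), 1)
})

test_that("identical children and outgroup reproduce the child architecture", {
  fix <- identicalTrio(n_chr = 20, n_pla = 6)
  st <- runPipeline(fix$genomes, fix$tree, method = "mp", outgroup = "C", seed = 1)
  roles <- st@replicons[["A_B"]]$roles
  expect_equal(nrow(roles), 2)
  expect_setequal(roles$n_genes, c(20L, 6L))
  reps <- split(st@replicons[["A_B"]]$assignment$family,
                st@replicons[["A_B"]]$assignment$replicon_id)
  expect_true(any(vapply(reps, function(r) setequal(r, paste0("f", 1:20)), TRUE)))
})

test_that("merge signal arithmetic follows the N1/N2 definition", {
  run <- data.frame(family = paste0("f", 1:10), strand = "+")
  a <- list(assignment = asg(paste0("f", 1:10), rep(c("R1", "R2"), c(6, 4))))
  p <- runMergeSignal(run, a)
  expect_equal(p$relative, 0.4)
  expect_equal(p$absolute, 10)
  ## single-replicon run: no proposal; short run: ignored
  a1 <- list(assignment = asg(paste0("f", 1:10), "R1"))
  expect_equal(nrow(runMergeSignal(run, a1)), 0)
  run3 <- run[1:3, ]
  expect_equal(nrow(runMergeSignal(run3, a)), 0)
  ## below the relative floor: dropped
  a2 <- list(assignment = asg(paste0("f", 1:20), rep(c("R1", "R2"), c(19, 1))))
  run20 <- data.frame(family = paste0("f", 1:20), strand = "+")
  expect_equal(nrow(runMergeSignal(run20, a2, low_floor = 0.1)), 0)
  expect_equal(nrow(runMergeSignal(run20, a2, low_floor = 0.01)), 1)
})

test_that("proposal clustering separates strong from weak and is deterministic", {
  strong <- data.frame(node = "n", r1 = "R1", r2 = paste0("S", 1:5),
                       relative = 0.45, absolute = 40)
  weak <- data.frame(node = "n", r1 = "R1", r2 = paste0("W", 1:5),
                     relative = 0.12, absolute = 4)
  dec <- clusterProposals(rbind(strong, weak), seed = 3)
  expect_true(all(dec$accepted[dec$r2 %in% strong$r2]))
  expect_false(any(dec$accepted[dec$r2 %in% weak$r2]))
  dec2 <- clusterProposals(rbind(strong, weak), seed = 3)
  expect_identical(dec, dec2)
  ## identical proposals: no separation, none accepted
  same <- data.frame(node = "n", r1 = "R1", r2 = paste0("S", 1:4),
                     relative = 0.3, absolute = 10)
  expect_false(any(clusterProposals(same, seed = 1)$accepted))
  ## strengths for the same pair are summed before clustering
  dup <- data.frame(node = "n", r1 = c("R1", "R1"), r2 = c("R2", "R2"),
                    relative = c(0.2, 0.4), absolute = c(5, 7))
  agg <- clusterProposals(dup, seed = 1)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$absolute, 12)
  expect_equal(agg$relative, 0.4)
})

test_that("merges apply transitively and absent proposals change nothing", {
  a <- list(assignment = asg(c("x", "y", "z"), c("R1", "R2", "R3")),
            roles = data.frame(replicon_id = c("R1", "R2", "R3"), role = "unknown"))
  merged <- applyMerges(a, data.frame(r1 = c("R1", "R2"), r2 = c("R2", "R3")))
  expect_equal(length(unique(merged$assignment$replicon_id)), 1)
  expect_identical(applyMerges(a, data.frame(r1 = character(), r2 = character())),
                   a)
})

test_that("chromosome restoration applies the 5% core rule as >= threshold", {
  core <- paste0("k", 1:100)
  ## replicon B carries exactly 5 core genes (5%), C carries 4 (4.9%-ish)
  a <- list(assignment = asg(
    c(paste0("k", 1:90), paste0("k", 91:95), paste0("k", 96:99), "u1"),
    rep(c("A", "B", "C"), c(90, 5, 5))))
  out <- restoreChromosomes(a, core)
  roles <- setNames(out$roles$role, out$roles$replicon_id)
  expect_equal(unname(roles["A"]), "main_chromosome")
  expect_equal(unname(roles["B"]), "secondary_chromosome")
  expect_equal(unname(roles["C"]), "plasmid")
  ## single replicon -> main chromosome
  s <- restoreChromosomes(list(assignment = asg("a", "R1")), core = "a")
  expect_equal(s$roles$role, "main_chromosome")
})

test_that("reconstructed families partition across replicons and merging never adds replicons", {
  sim <- simulateGenomes(simConfig(n_leaves = 7, n_outgroup = 2,
                                   root_chromosome = 50, root_plasmid = 12,
                                   seed = 23))
  gen <- simGenomeSet(sim, "leaves")
  st <- runPipeline(gen, sim@tree, method = "mp", seed = 2)
  props <- attr(st@replicons, "proposals")
  for (nd in internalIds(sim@tree)) {
    a <- st@replicons[[nd]]$assignment
    expect_setequal(a$family, st@genes[[nd]])
    expect_equal(anyDuplicated(a$family), 0)
  }
})
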