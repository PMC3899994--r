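## Small in-code fixtures shared across the suite.

## a genome table row block for one linear replicon given signed families,
## e.g. c("+1", "-2", "*") -- "*" rows become singleton genes
repliconRows <- function(genome_id, replicon_id, signed, role = "plasmid",
                         circular = FALSE) {
  fam <- sub("^[+-]", "", signed)
  strand <- ifelse(grepl("^-", signed), "-", "+")
  strand[fam == "*"] <- "+"
  data.frame(genome_id = genome_id, replicon_id = replicon_id,
             replicon_role = role, circular = circular,
             position = seq_along(signed), strand = strand,
             family_id = fam,
             gene_id = paste(genome_id, replicon_id, seq_along(signed), sep = "."),
             stringsAsFactors = FALSE)
}

## NGP data.frame (as consumed by buildAdjacencyGraph) from canonical keys
ngpTable <- function(keys, score = 1) {
  d <- AncestralGenomes:::.parseNGP(keys)
  data.frame(d[, c("key", "fam1", "end1", "fam2", "end2")],
             score = rep_len(score, length(keys)), stringsAsFactors = FALSE)
}

## genome set with three identical genomes (two children + outgroup) laid
## out as one chromosome and one plasmid of the given sizes
identicalTrio <- function(n_chr = 30, n_pla = 8, seed = 1) {
  set.seed(seed)
  strand <- sample(c("+", "-"), n_chr + n_pla, replace = TRUE)
  mk <- function(gid) {
    chr <- data.frame(genome_id = gid, replicon_id = "chr",
                      replicon_role = "main_chromosome", circular = FALSE,
                      position = 1:n_chr, strand = strand[1:n_chr],
                      family_id = paste0("f", 1:n_chr),
                      gene_id = paste0(gid, ".c", 1:n_chr),
                      stringsAsFactors = FALSE)
    if (n_pla == 0) return(chr)
    rbind(chr,
          data.frame(genome_id = gid, replicon_id = "pla",
                     replicon_role = "plasmid", circular = FALSE,
                     position = 1:n_pla, strand = strand[n_chr + 1:n_pla],
                     family_id = paste0("f", n_chr + 1:n_pla),
                     gene_id = paste0(gid, ".p", 1:n_pla),
                     stringsAsFactors = FALSE))
  }
  list(genomes = GenomeSet(rbind(mk("A"), mk("B"), mk("C"))),
       tree = speciesTree(ape::read.tree(text = "((A:1,B:1):1,C:2);")))
}

zeroRates <- list(gene_gain = 0, gene_loss = 0, duplication = 0, reversal = 0,
                  translocation = 0, transposition = 0, replicon_gain = 0,
                  replicon_merge = 0, replicon_split = 0, replicon_loss = 0)

geneRatesOnly <- function(scale = 1) {
  list(gene_gain = 60 * scale, gene_loss = 60 * scale,
       duplication = 20 * scale, reversal = 40 * scale,
       translocation = 1 * scale, transposition = 8 * scale,
       replicon_gain = 0, replicon_merge = 0, replicon_split = 0,
       replicon_loss = 0)
}
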