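## Gene-order table I/O and GenomeSet accessors.
##
## The on-disk dialect is a UTF-8 TSV with header
##   genome_id replicon_id replicon_role circular position strand family_id gene_id
## and "#" comment lines. One row per gene; positions are 1-based and
## contiguous along each replicon; singleton genes carry family_id "*".

#' Construct a GenomeSet from a gene table
#'
#' @param genes data.frame with the gene-order columns (`genome_id`,
#'   `replicon_id`, `replicon_role`, `circular`, `position`, `strand`,
#'   `family_id`, `gene_id`).
#' @return a [GenomeSet-class].
#' @export
GenomeSet <- function(genes = data.frame()) {
  if (nrow(genes) == 0) {
    genes <- data.frame(genome_id = character(), replicon_id = character(),
                        replicon_role = character(), circular = logical(),
                        position = integer(), strand = character(),
                        family_id = character(), gene_id = character(),
                        stringsAsFactors = FALSE)
  } else {
    genes <- genes[GENE_TABLE_COLUMNS]
    genes$position <- as.integer(genes$position)
    genes$circular <- as.logical(genes$circular)
    for (col in setdiff(GENE_TABLE_COLUMNS, c("position", "circular")))
      genes[[col]] <- as.character(genes[[col]])
    ord <- order(genes$genome_id, genes$replicon_id, genes$position)
    genes <- genes[ord, , drop = FALSE]
    rownames(genes) <- NULL
  }
  obj <- new("GenomeSet", genes = genes)
  validObject(obj)
  obj
}

#' Read a gene-order table
#'
#' @param path path to the TSV file.
#' @return a validated [GenomeSet-class]. Paralog violations (a
#'   non-singleton family occurring twice in one genome) and non-contiguous
#'   positions raise errors naming the offending genome/replicon.
#' @examples
#' gs <- readGeneTable(system.file("extdata", "example_genomes.tsv",
#'                                 package = "AncestralGenomes"))
#' gs
#' @export
readGeneTable <- function(path) {
  g <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  missing <- setdiff(GENE_TABLE_COLUMNS, names(g))
  if (length(missing))
    stop("format error: missing columns ", paste(missing, collapse = ", "))
  g$position <- as.integer(g$position)
  g$circular <- g$circular %in% c("TRUE", "true", "1", "T")
  GenomeSet(g)
}

#' Write a gene-order table
#'
#' @param x a [GenomeSet-class].
#' @param path output path.
#' @return `path`, invisibly. The file is re-readable by [readGeneTable()]
#'   with identical content (row order is canonical: genome, replicon,
#'   position).
#' @export
writeGeneTable <- function(x, path) {
  write.table(x@genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname GenomeSet
#' @param x a `GenomeSet`.
#' @export
genomeIds <- function(x) unique(x@genes$genome_id)

#' @rdname GenomeSet
#' @export
geneTable <- function(x) x@genes

#' Family alphabet and core families
#'
#' `familyAlphabet` returns all non-singleton family IDs observed in the
#' set; `coreFamilies` the subset present in every genome.
#'
#' @param x a [GenomeSet-class].
#' @return character vector of family IDs.
#' @export
familyAlphabet <- function(x) {
  sort(setdiff(unique(x@genes$family_id), SINGLETON))
}

#' @rdname familyAlphabet
#' @export
coreFamilies <- function(x) {
  g <- x@genes[x@genes$family_id != SINGLETON, ]
  ng <- length(unique(x@genes$genome_id))
  tab <- table(unique(g[, c("genome_id", "family_id")])$family_id)
  sort(names(tab)[tab == ng])
}

#' Subset a GenomeSet by genome
#' @param x a [GenomeSet-class].
#' @param ids genome ids to keep.
#' @export
subsetGenomes <- function(x, ids) {
  GenomeSet(x@genes[x@genes$genome_id %in% ids, , drop = FALSE])
}

## ---- internal list representation ------------------------------------
## genome: list(genome_id, replicons = named list(replicon_id ->
##   list(role, circular, family = chr, strand = chr, gene_id = chr)))
## Used by the simulator and the reconstruction internals; positions are
## implicit in vector order.

.genomeList <- function(x) {
  g <- x@genes
  out <- list()
  for (gid in unique(g$genome_id)) {
    gg <- g[g$genome_id == gid, , drop = FALSE]
    reps <- list()
    for (rid in unique(gg$replicon_id)) {
      rr <- gg[gg$replicon_id == rid, , drop = FALSE]
      rr <- rr[order(rr$position), , drop = FALSE]
      reps[[rid]] <- list(role = rr$replicon_role[1], circular = rr$circular[1],
                          family = rr$family_id, strand = rr$strand,
                          gene_id = rr$gene_id)
    }
    out[[gid]] <- list(genome_id = gid, replicons = reps)
  }
  out
}

.genomeSetFromList <- function(genomes) {
  rows <- list()
  for (gm in genomes) {
    for (rid in names(gm$replicons)) {
      rep <- gm$replicons[[rid]]
      n <- length(rep$family)
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gm$genome_id, replicon_id = rid,
        replicon_role = rep$role, circular = isTRUE(rep$circular),
        position = seq_len(n), strand = rep$strand,
        family_id = rep$family,
        gene_id = if (!is.null(rep$gene_id)) rep$gene_id else
          paste(gm$genome_id, rid, seq_len(n), sep = "."),
        stringsAsFactors = FALSE)
    }
  }
  GenomeSet(do.call(rbind, rows))
}

## leaf replicon assignment: data.frame(family, replicon_id) for one genome
.leafAssignment <- function(x, genome_id) {
  g <- x@genes
  g <- g[g$genome_id == genome_id & g$family_id != SINGLETON, , drop = FALSE]
  roles <- unique(g[, c("replicon_id", "replicon_role")])
  list(assignment = data.frame(family = g$family_id, replicon_id = g$replicon_id,
                               stringsAsFactors = FALSE),
       roles = data.frame(replicon_id = roles$replicon_id, role = roles$replicon_role,
                          stringsAsFactors = FALSE))
}

#' Validate a species tree against a genome set
#'
#' Checks the leaf/genome binding both ways and summarizes the character
#' alphabet. Problems are reported, not thrown, so a driver can decide
#' what is fatal.
#'
#' @param tree a [SpeciesTree-class].
#' @param genomes a [GenomeSet-class].
#' @return list with `issues` (character vector, empty when clean; entries
#'   prefixed "fatal:" prevent reconstruction), `n_families`, `n_core`,
#'   `n_genomes`, `n_leaves`.
#' @export
validateInputs <- function(tree, genomes) {
  issues <- character()
  leaves <- leafIds(tree)
  gids <- genomeIds(genomes)
  for (l in setdiff(leaves, gids))
    issues <- c(issues, sprintf("fatal: tree leaf '%s' has no genome", l))
  for (g in setdiff(gids, leaves))
    issues <- c(issues, sprintf("genome '%s' is not a tree leaf (ignored)", g))
  list(issues = issues,
       n_families = length(familyAlphabet(genomes)),
       n_core = length(coreFamilies(genomes)),
       n_genomes = length(gids), n_leaves = length(leaves))
}
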