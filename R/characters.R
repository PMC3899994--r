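## Binary presence characters: gene-content and neighboring-gene-pair (NGP)
## matrices.
##
## Every gene is represented by its two ends -- head (5', "h") and tail
## (3', "t") -- so an adjacency between two genes carries orientation as
## well. A gene end is written "<family>|h" or "<family>|t"; an NGP is the
## canonical (sorted) unordered pair of the two facing ends, which makes
## the feature invariant under the reading direction of the replicon.

.END_SEP <- "|"
.NGP_SEP <- "~"

geneEnd <- function(family, end) paste(family, end, sep = .END_SEP)

.parseEnd <- function(e) {
  parts <- strsplit(e, .END_SEP, fixed = TRUE)
  list(family = vapply(parts, `[`, "", 1L), end = vapply(parts, `[`, "", 2L))
}

#' Oriented ends of a gene
#'
#' For a gene on the forward strand the left (upstream) end is its head
#' (5') and the right end its tail (3'); on the reverse strand the two are
#' swapped. Vectorized.
#'
#' @param family family ID(s); the singleton symbol is not allowed.
#' @param strand "+" or "-" per gene.
#' @return list with character vectors `left` and `right` of gene-end keys.
#' @export
orientedEnds <- function(family, strand) {
  if (any(family == SINGLETON)) stop("singleton genes have no reconstructable ends")
  left <- ifelse(strand == "+", geneEnd(family, "h"), geneEnd(family, "t"))
  right <- ifelse(strand == "+", geneEnd(family, "t"), geneEnd(family, "h"))
  list(left = left, right = right)
}

#' Canonical NGP key for a pair of facing gene ends
#'
#' Order-insensitive and reading-direction-insensitive: the two ends are
#' sorted lexicographically and joined, so the same physical adjacency
#' always yields one key.
#'
#' @param a,b gene-end keys (from [orientedEnds()]); must belong to two
#'   distinct families.
#' @return character NGP key(s).
#' @export
canonicalNGP <- function(a, b) {
  fa <- .parseEnd(a)$family; fb <- .parseEnd(b)$family
  if (any(fa == fb))
    stop("self-adjacency: both ends belong to family ", fa[fa == fb][1])
  ifelse(a < b, paste(a, b, sep = .NGP_SEP), paste(b, a, sep = .NGP_SEP))
}

.parseNGP <- function(key) {
  parts <- strsplit(key, .NGP_SEP, fixed = TRUE)
  e1 <- vapply(parts, `[`, "", 1L); e2 <- vapply(parts, `[`, "", 2L)
  p1 <- .parseEnd(e1); p2 <- .parseEnd(e2)
  data.frame(key = key, end_a = e1, end_b = e2,
             fam1 = p1$family, end1 = p1$end, fam2 = p2$family, end2 = p2$end,
             stringsAsFactors = FALSE)
}

## canonical NGP keys of one replicon (family/strand vectors, circular flag)
.repliconNGPs <- function(family, strand, circular, skip_singletons = FALSE) {
  keep <- family != SINGLETON
  if (skip_singletons) {
    family <- family[keep]; strand <- strand[keep]
    keep <- rep(TRUE, length(family))
  }
  n <- length(family)
  if (n < 2) return(character(0))
  ends <- rep("", n); ends_l <- rep("", n)
  fb <- which(keep)
  if (length(fb)) {
    oe <- orientedEnds(family[fb], strand[fb])
    ends[fb] <- oe$right; ends_l[fb] <- oe$left
  }
  i <- seq_len(n - 1); j <- i + 1
  if (isTRUE(circular)) { i <- c(i, n); j <- c(j, 1L) }
  ok <- keep[i] & keep[j] & family[i] != family[j]
  i <- i[ok]; j <- j[ok]
  if (!length(i)) return(character(0))
  unique(canonicalNGP(ends[i], ends_l[j]))
}

#' NGP keys observed in one genome
#'
#' @param x a [GenomeSet-class].
#' @param genome_id genome to scan.
#' @param skip_singletons if `TRUE`, runs of singleton genes are
#'   transparent: two family-bearing genes separated only by singletons
#'   form an NGP. Default `FALSE` (strict physical adjacency).
#' @return character vector of canonical NGP keys.
#' @export
genomeNGPs <- function(x, genome_id, skip_singletons = FALSE) {
  gl <- .genomeList(subsetGenomes(x, genome_id))[[genome_id]]
  keys <- character(0)
  for (rep in gl$replicons)
    keys <- c(keys, .repliconNGPs(rep$family, rep$strand, rep$circular,
                                  skip_singletons))
  sort(unique(keys))
}

#' Gene-content presence matrix
#'
#' @param x a [GenomeSet-class].
#' @return binary matrix, one row per non-singleton family, one column per
#'   genome; 1 iff the family occurs in the genome.
#' @export
geneContentMatrix <- function(x) {
  fams <- familyAlphabet(x)
  gids <- genomeIds(x)
  m <- matrix(0L, length(fams), length(gids), dimnames = list(fams, gids))
  g <- x@genes[x@genes$family_id != SINGLETON, ]
  m[cbind(match(g$family_id, fams), match(g$genome_id, gids))] <- 1L
  m
}

#' NGP presence matrix
#'
#' @inheritParams genomeNGPs
#' @return binary matrix, one row per canonical NGP observed in at least
#'   one genome, one column per genome. The attribute `"ends"` carries the
#'   parsed end/family table for the row keys.
#' @export
ngpMatrix <- function(x, skip_singletons = FALSE) {
  gids <- genomeIds(x)
  per <- lapply(gids, function(g) genomeNGPs(x, g, skip_singletons))
  keys <- sort(unique(unlist(per)))
  m <- matrix(0L, length(keys), length(gids), dimnames = list(keys, gids))
  for (k in seq_along(gids)) m[match(per[[k]], keys), k] <- 1L
  attr(m, "ends") <- if (length(keys)) .parseNGP(keys) else NULL
  m
}

#' Export a presence matrix as TSV
#'
#' @param m matrix from [geneContentMatrix()] or [ngpMatrix()].
#' @param path output path.
#' @export
writePresenceMatrix <- function(m, path) {
  df <- data.frame(character = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
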