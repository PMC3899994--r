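## Species tree construction and navigation.
##
## Internally every node is addressed by its ape index (leaves 1..n, then
## internal nodes); the index list built here caches parents, children in
## input order, branch lengths and the generated node labels so traversal
## code never touches the edge matrix directly.

.buildTreeIndex <- function(ph) {
  ntip <- ape::Ntip(ph)
  ntot <- ntip + ph$Nnode
  parent <- rep(NA_integer_, ntot)
  brlen <- rep(NA_real_, ntot)
  children <- vector("list", ntot)
  for (i in seq_len(ntot)) children[[i]] <- integer(0)
  for (e in seq_len(nrow(ph$edge))) {
    p <- ph$edge[e, 1]; c <- ph$edge[e, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
    if (!is.null(ph$edge.length)) brlen[c] <- ph$edge.length[e]
  }
  root <- which(is.na(parent))[1]
  ## postorder over all nodes (children before parents), iterative DFS
  post <- integer(0)
  stack <- root; emit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    emit <- c(emit, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(emit)
  ## labels: leaves = tip labels; internal = underscore join of descendant
  ## leaves in left-to-right order
  leafseq <- vector("list", ntot)
  labels <- character(ntot)
  labels[seq_len(ntip)] <- ph$tip.label
  for (v in post) {
    if (v <= ntip) {
      leafseq[[v]] <- ph$tip.label[v]
    } else {
      leafseq[[v]] <- unlist(lapply(children[[v]], function(c) leafseq[[c]]))
      labels[v] <- paste(leafseq[[v]], collapse = "_")
    }
  }
  list(ntip = ntip, ntot = ntot, root = root, parent = parent,
       children = children, brlen = brlen, labels = labels,
       postorder = post, internal = setdiff(seq_len(ntot), seq_len(ntip)),
       id2idx = setNames(seq_len(ntot), labels))
}

#' Construct a SpeciesTree from an ape phylo object
#'
#' Validates that the tree is rooted and strictly bifurcating and generates
#' internal node identifiers by joining descendant leaf labels with
#' underscores (left to right), e.g. the parent of leaves `A` and `B` is
#' `A_B`.
#'
#' @param ph an `ape::phylo` object.
#' @return a [SpeciesTree-class] object.
#' @export
speciesTree <- function(ph) {
  if (!inherits(ph, "phylo")) stop("'ph' must be an ape phylo object")
  if (any(grepl("_", ph$tip.label, fixed = TRUE)))
    stop("leaf labels must not contain '_' (reserved for internal node ids)")
  tab <- tabulate(ph$edge[, 1], nbins = ape::Ntip(ph) + ph$Nnode)
  internal <- (ape::Ntip(ph) + 1):(ape::Ntip(ph) + ph$Nnode)
  if (any(tab[internal] != 2))
    stop("unsupported topology: tree must be strictly bifurcating (polytomy found)")
  obj <- new("SpeciesTree", phylo = ph, index = .buildTreeIndex(ph))
  validObject(obj)
  obj
}

#' Read a rooted bifurcating species tree from a Newick file
#'
#' @param path path to a Newick file (one tree). Branch lengths are
#'   required for maximum-likelihood reconstruction; maximum parsimony
#'   tolerates their absence.
#' @return a [SpeciesTree-class].
#' @export
readSpeciesTree <- function(path) {
  ph <- ape::read.tree(path)
  if (is.null(ph)) stop("could not parse Newick file: ", path)
  if (inherits(ph, "multiPhylo")) ph <- ph[[1]]
  if (is.null(ph$tip.label) || any(is.na(ph$tip.label)) || any(!nzchar(ph$tip.label)))
    stop("format error: every leaf must be labeled")
  speciesTree(ph)
}

#' @rdname speciesTree
#' @param x a `SpeciesTree`.
#' @export
rootId <- function(x) x@index$labels[x@index$root]

#' Node identifiers of a SpeciesTree
#'
#' @param x a `SpeciesTree`.
#' @return `nodeIds`: all node ids (leaves then internal); `leafIds`: leaf
#'   ids; `internalIds`: internal node ids.
#' @export
nodeIds <- function(x) x@index$labels

#' @rdname nodeIds
#' @export
leafIds <- function(x) x@index$labels[seq_len(x@index$ntip)]

#' @rdname nodeIds
#' @export
internalIds <- function(x) x@index$labels[x@index$internal]

#' Children / parent / branch length lookup by node id
#'
#' @param x a `SpeciesTree`.
#' @param id node identifier.
#' @return `childIds`: character vector of child ids (empty for a leaf);
#'   `parentId`: parent id or `NA` for the root; `branchLengthOf`: branch
#'   length of the edge above `id`.
#' @export
childIds <- function(x, id) {
  idx <- x@index$id2idx[[id]]
  x@index$labels[x@index$children[[idx]]]
}

#' @rdname childIds
#' @export
parentId <- function(x, id) {
  p <- x@index$parent[x@index$id2idx[[id]]]
  if (is.na(p)) NA_character_ else x@index$labels[p]
}

#' @rdname childIds
#' @export
branchLengthOf <- function(x, id) x@index$brlen[x@index$id2idx[[id]]]

#' Sibling of a node (the other child of its parent)
#' @inheritParams childIds
#' @return node id, or `NA` for the root.
#' @export
siblingId <- function(x, id) {
  p <- parentId(x, id)
  if (is.na(p)) return(NA_character_)
  setdiff(childIds(x, p), id)
}

## internal ids in bottom-up (children before parents) order
.internalPostorder <- function(x) {
  idx <- x@index$postorder
  x@index$labels[idx[idx > x@index$ntip]]
}

## leaves under a node
.leavesUnder <- function(x, id) {
  strsplit(id, "_", fixed = TRUE)[[1]]
}
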