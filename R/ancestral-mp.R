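## Fitch-style maximum parsimony for binary presence characters, vectorized
## over characters. State sets are bit-encoded: 1 = {absent}, 2 = {present},
## 3 = {absent, present}.

#' Maximum-parsimony ancestral presence reconstruction
#'
#' Fitch down-pass (intersection of the children's state sets where
#' non-empty, else union) followed by an up-pass that resolves ambiguity by
#' preferring the parent's resolved state; ambiguity at the root resolves
#' to absence (the conservative choice, in line with the stringent
#' presence cutoffs used elsewhere in the pipeline).
#'
#' @param tree a [SpeciesTree-class].
#' @param mat binary presence matrix, characters x genomes
#'   ([geneContentMatrix()] / [ngpMatrix()]); columns must cover all leaves.
#' @return list with `states` (matrix, characters x internal node ids, in
#'   \{0,1\}) and `changes` (per-character minimum change count).
#' @export
mpReconstruct <- function(tree, mat) {
  ix <- tree@index
  nchar_ <- nrow(mat)
  leaves <- seq_len(ix$ntip)
  S <- matrix(0L, ix$ntot, nchar_)
  miss <- setdiff(ix$labels[leaves], colnames(mat))
  if (length(miss)) stop("matrix lacks leaf columns: ", paste(miss, collapse = ", "))
  for (l in leaves) S[l, ] <- ifelse(mat[, ix$labels[l]] == 1L, 2L, 1L)
  changes <- integer(nchar_)
  post <- ix$postorder[ix$postorder > ix$ntip]
  for (v in post) {
    ch <- ix$children[[v]]
    a <- S[ch[1], ]; b <- S[ch[2], ]
    inter <- bitwAnd(a, b)
    un <- bitwOr(a, b)
    empty <- inter == 0L
    changes <- changes + as.integer(empty)
    S[v, ] <- ifelse(empty, un, inter)
  }
  Fin <- matrix(0L, ix$ntot, nchar_)
  for (l in leaves) Fin[l, ] <- S[l, ] - 1L
  for (v in rev(post)) {
    sv <- S[v, ]
    if (v == ix$root) {
      Fin[v, ] <- ifelse(sv == 3L, 0L, sv - 1L)
    } else {
      fp <- Fin[ix$parent[v], ]
      Fin[v, ] <- ifelse(sv == 3L, fp, sv - 1L)
    }
  }
  internal <- ix$internal
  states <- t(Fin[internal, , drop = FALSE])
  dimnames(states) <- list(rownames(mat), ix$labels[internal])
  list(states = states, changes = setNames(changes, rownames(mat)))
}
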