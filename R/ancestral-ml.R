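## Two-state continuous-time Markov model for presence/absence characters:
## Felsenstein pruning likelihood, ML rate fitting, and marginal ancestral
## posteriors. All computations are vectorized across characters (partial
## likelihoods are characters x 2 matrices per node, with per-character
## log-scaling against underflow).

#' Transition probability matrix of the two-state gain/loss model
#'
#' States are 0 = absent, 1 = present; `q01` is the gain rate and `q10`
#' the loss rate per unit branch length. Closed form of the 2-state CTMC.
#'
#' @param q01,q10 non-negative rates, not both zero.
#' @param t branch length.
#' @return 2x2 matrix `P[s_from + 1, s_to + 1]`.
#' @export
transitionMatrix <- function(q01, q10, t) {
  s <- q01 + q10
  e <- exp(-s * t)
  matrix(c(q10 / s + q01 / s * e, q10 / s * (1 - e),
           q01 / s * (1 - e),     q01 / s + q10 / s * e),
         2, 2, byrow = FALSE)
}

.stationary <- function(q01, q10) c(q10, q01) / (q01 + q10)

.branchLengths <- function(tree, eps = 1e-6) {
  bl <- tree@index$brlen
  bl[is.na(bl) | bl <= 0] <- eps
  bl
}

## Downward (subtree) partial likelihoods for all characters at all nodes.
## Returns list(partials = list of nchar x 2 matrices, logscale = nchar
## vector accumulated at the root, per-node logscale matrix for marginals).
.downPartials <- function(tree, mat, q01, q10, eps = 1e-6) {
  ix <- tree@index
  nchar_ <- nrow(mat)
  bl <- .branchLengths(tree, eps)
  P <- vector("list", ix$ntot)
  for (v in seq_len(ix$ntot))
    if (!is.na(ix$parent[v])) P[[v]] <- transitionMatrix(q01, q10, bl[v])
  L <- vector("list", ix$ntot)
  lsc <- matrix(0, ix$ntot, nchar_)   # cumulative log-scaler per node/char
  for (l in seq_len(ix$ntip)) {
    x <- mat[, ix$labels[l]]
    L[[l]] <- cbind(as.numeric(x == 0L), as.numeric(x == 1L))
  }
  post <- ix$postorder[ix$postorder > ix$ntip]
  for (v in post) {
    ch <- ix$children[[v]]
    a <- ch[1]; b <- ch[2]
    Lv <- (L[[a]] %*% t(P[[a]])) * (L[[b]] %*% t(P[[b]]))
    sc <- pmax(Lv[, 1], Lv[, 2])
    sc[sc == 0] <- 1
    L[[v]] <- Lv / sc
    lsc[v, ] <- lsc[a, ] + lsc[b, ] + log(sc)
  }
  list(L = L, lsc = lsc, P = P)
}

#' Pruning log-likelihood of presence characters
#'
#' @param tree a [SpeciesTree-class] with branch lengths (zero/missing
#'   lengths are replaced by `eps`).
#' @param mat binary matrix, characters x genomes.
#' @param q01,q10 gain/loss rates.
#' @param eps substitute for non-positive branch lengths.
#' @return numeric vector of per-character log-likelihoods, with the root
#'   prior set to the stationary distribution of the rate model.
#' @export
pruneLikelihood <- function(tree, mat, q01, q10, eps = 1e-6) {
  dp <- .downPartials(tree, mat, q01, q10, eps)
  root <- tree@index$root
  pi <- .stationary(q01, q10)
  lik <- dp$L[[root]] %*% pi
  setNames(as.numeric(log(lik) + dp$lsc[root, ]), rownames(mat))
}

#' Fit gain/loss rates by maximum likelihood
#'
#' Maximizes the summed pruning log-likelihood over all characters, with a
#' bounded multi-start search on the log-rate scale. With a single shared
#' model per character class this is the default rate protocol; rare
#' characters do not support per-character fits.
#'
#' @inheritParams pruneLikelihood
#' @param lower,upper rate bounds.
#' @param starts matrix of starting (q01, q10) pairs; default small grid.
#' @return list with `q01`, `q10`, `logLik`.
#' @export
fitRates <- function(tree, mat, lower = 1e-6, upper = 1e3,
                     starts = NULL, eps = 1e-6) {
  if (nrow(mat) == 0) stop("no characters to fit")
  rng <- apply(mat[, leafIds(tree), drop = FALSE], 1, function(r) length(unique(r)))
  if (all(rng == 1))
    warning("all characters constant across leaves; rates are not identifiable ",
            "(boundary minimum-rate model returned)")
  nll <- function(par) {
    q <- exp(par)
    -sum(pruneLikelihood(tree, mat, q[1], q[2], eps))
  }
  if (is.null(starts))
    starts <- as.matrix(expand.grid(q01 = c(0.05, 0.5, 5), q10 = c(0.05, 0.5, 5)))[c(1, 5, 9, 3, 7), ]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(log(as.numeric(starts[i, ])), nll, method = "L-BFGS-B",
            lower = log(lower), upper = log(upper)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("rate optimization failed")
  q <- exp(best$par)
  list(q01 = q[1], q10 = q[2], logLik = -best$value)
}

#' Marginal ancestral posteriors of presence
#'
#' Standard marginal ancestral state reconstruction: the posterior at a
#' node combines the downward (subtree) partial likelihoods with the
#' upward contribution of the rest of the tree, under the stationary root
#' prior.
#'
#' @inheritParams pruneLikelihood
#' @return matrix of P(present), characters x internal node ids, values in
#'   \[0, 1\].
#' @export
marginalPosteriors <- function(tree, mat, q01, q10, eps = 1e-6) {
  ix <- tree@index
  nchar_ <- nrow(mat)
  dp <- .downPartials(tree, mat, q01, q10, eps)
  pi <- .stationary(q01, q10)
  A <- vector("list", ix$ntot)
  A[[ix$root]] <- matrix(pi, nchar_, 2, byrow = TRUE)
  pre <- rev(ix$postorder)              # parents before children
  for (v in pre) {
    if (v <= ix$ntip) next
    ch <- ix$children[[v]]
    contrib <- lapply(ch, function(c) dp$L[[c]] %*% t(dp$P[[c]]))
    for (k in 1:2) {
      c <- ch[k]; sib <- contrib[[3 - k]]
      Ac <- (A[[v]] * sib) %*% dp$P[[c]]
      sc <- pmax(Ac[, 1], Ac[, 2]); sc[sc == 0] <- 1
      A[[c]] <- Ac / sc
    }
  }
  internal <- ix$internal
  out <- matrix(NA_real_, nchar_, length(internal),
                dimnames = list(rownames(mat), ix$labels[internal]))
  for (j in seq_along(internal)) {
    v <- internal[j]
    joint <- A[[v]] * dp$L[[v]]
    out[, j] <- joint[, 2] / (joint[, 1] + joint[, 2])
  }
  out
}

#' Call presence of characters at ancestral nodes
#'
#' ML: a character is present where its marginal posterior is at or above
#' the cutoff (`gene_occurrence_cutoff` for families, `gene_pair_cutoff`
#' for NGPs). MP: present where the resolved state is 1. A consistency
#' filter then drops any called NGP whose member families are not both
#' called present at that node.
#'
#' @param gene_states matrix families x internal nodes: posteriors (ML) or
#'   0/1 states (MP).
#' @param ngp_states matrix NGP keys x internal nodes, same convention.
#' @param ngp_ends data.frame describing the NGP rows (attribute `"ends"`
#'   of [ngpMatrix()]).
#' @param method "mp" or "ml".
#' @param gene_occurrence_cutoff,gene_pair_cutoff posterior thresholds in
#'   (0,1); both default 0.9. Ignored under MP.
#' @return list per internal node id: `genes` (character vector),
#'   `ngps` (data.frame `key, fam1, end1, fam2, end2, score`), and
#'   `dropped_ngps` (keys removed by the consistency filter).
#' @export
callPresence <- function(gene_states, ngp_states, ngp_ends, method = c("ml", "mp"),
                         gene_occurrence_cutoff = 0.9, gene_pair_cutoff = 0.9) {
  method <- match.arg(method)
  nodes <- colnames(gene_states)
  out <- list()
  for (nd in nodes) {
    gs <- gene_states[, nd]
    if (method == "ml") {
      fams <- rownames(gene_states)[gs >= gene_occurrence_cutoff]
    } else {
      fams <- rownames(gene_states)[gs == 1]
    }
    if (!is.null(ngp_states) && nrow(ngp_states)) {
      ps <- ngp_states[, nd]
      keep <- if (method == "ml") ps >= gene_pair_cutoff else ps == 1
      keys <- rownames(ngp_states)[keep]
      score <- if (method == "ml") ps[keep] else rep(1, sum(keep))
      ed <- ngp_ends[match(keys, ngp_ends$key), , drop = FALSE]
      consistent <- ed$fam1 %in% fams & ed$fam2 %in% fams
      ngps <- data.frame(ed[consistent, c("key", "fam1", "end1", "fam2", "end2")],
                         score = score[consistent], stringsAsFactors = FALSE)
      rownames(ngps) <- NULL
      dropped <- keys[!consistent]
    } else {
      ngps <- data.frame(key = character(), fam1 = character(), end1 = character(),
                         fam2 = character(), end2 = character(), score = numeric(),
                         stringsAsFactors = FALSE)
      dropped <- character(0)
    }
    out[[nd]] <- list(genes = fams, ngps = ngps, dropped_ngps = dropped)
  }
  out
}
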