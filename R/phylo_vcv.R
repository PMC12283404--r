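#' Phylogenetic variance-covariance matrix under Brownian motion
#'
#' Builds the among-species covariance matrix implied by Brownian-motion
#' evolution on a rooted tree with branch lengths: `C[i, j]` is the shared
#' root-to-MRCA path length of species i and j, and `C[i, i]` is the
#' root-to-tip path length of species i. Rows and columns follow `taxa`;
#' tips of the tree not listed in `taxa` are ignored.
#'
#' Memory grows as the square of the number of taxa; requests beyond
#' `getOption("phyrange.max_tips", 5000)` raise an error advising tree
#' pruning rather than silently allocating huge matrices.
#'
#' @param tree A `phylo` tree with branch lengths (polytomies allowed).
#' @param taxa Ordered character vector of tip labels; defaults to all tips.
#' @return A symmetric positive semi-definite matrix with dimnames `taxa`.
#' @export
phylo_vcv <- function(tree, taxa = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  .assert(!is.null(tree$edge.length) && !anyNA(tree$edge.length),
          "tree has missing branch lengths; covariance undefined")
  .assert(all(tree$edge.length >= 0), "negative branch lengths")
  missing_taxa <- setdiff(taxa, tree$tip.label)
  .assert(length(missing_taxa) == 0, "taxa not in tree: %s",
          paste(missing_taxa, collapse = ", "))
  cap <- getOption("phyrange.max_tips", 5000)
  .assert(length(taxa) <= cap,
          paste0("%d taxa exceed the O(n^2) covariance cap of %d; ",
                 "prune the tree or raise options(phyrange.max_tips=)"),
          length(taxa), cap)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # node depths from the root, preorder
  depth <- numeric(nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    depth[pre$edge[e, 2]] <- depth[pre$edge[e, 1]] + pre$edge.length[e]
  }
  # tip sets per node, postorder accumulation
  tips_under <- vector("list", nnode)
  for (i in seq_len(ntip)) tips_under[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  children <- split(post$edge[, 2], post$edge[, 1])
  C <- matrix(0, ntip, ntip)
  for (v in unique(post$edge[, 1])) {
    kids <- children[[as.character(v)]]
    sets <- tips_under[kids]
    # MRCA of tips in different child subtrees is v
    if (length(sets) > 1) {
      for (a in seq_len(length(sets) - 1)) {
        for (b in seq(a + 1, length(sets))) {
          C[sets[[a]], sets[[b]]] <- depth[v]
          C[sets[[b]], sets[[a]]] <- depth[v]
        }
      }
    }
    tips_under[[v]] <- unlist(sets, use.names = FALSE)
  }
  diag(C) <- depth[seq_len(ntip)]
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C[taxa, taxa, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lam`, leaving the diagonal
#' unchanged. `lam = 1` returns the full Brownian structure, `lam = 0` the
#' phylogenetically independent (diagonal) structure.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lam Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lam) {
  .assert(is.numeric(lam) && length(lam) == 1 && is.finite(lam) &&
            lam >= 0 && lam <= 1, "lambda must be a scalar in [0, 1]")
  out <- lam * C
  diag(out) <- diag(C)
  out
}
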