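#' Parse a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] accepting either a Newick string or
#' a file path. Branch lengths may be absent (assign them with
#' [grafen_branch_lengths()]).
#'
#' @param text Newick string (ending in `;`) or path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  tr <- if (length(text) == 1 && grepl(";", text, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    ape::read.tree(text)
  }
  if (is.null(tr)) stop("malformed Newick string", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels", call. = FALSE)
  tr
}

#' Grafen branch lengths
#'
#' Assigns each internal node the height
#' `((number of descendant tips - 1) / (S - 1))^rho`, tips at height 0 and
#' the root at height 1; a branch's length is the height difference between
#' its ends. The result is ultrametric with total depth 1.
#'
#' @param tree An [ape::phylo] tree (branch lengths, if any, are ignored).
#' @param rho Power applied to the scaled heights (default 1).
#' @return The tree with Grafen branch lengths.
#' @export
grafen_branch_lengths <- function(tree, rho = 1) {
  if (ape::Ntip(tree) < 2) stop("need at least 2 tips", call. = FALSE)
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Phylogenetic correlation matrix
#'
#' For an ultrametric tree of depth T, the correlation between two species is
#' the depth of their most recent common ancestor divided by T — the shared
#' fraction of their root-to-tip paths under a Brownian-motion model. The
#' matrix is symmetric, has unit diagonal, and is positive semi-definite.
#'
#' @param tree An ultrametric [ape::phylo] tree with branch lengths.
#' @param tol Ultrametricity tolerance on root-to-tip depth spread.
#' @return An S x S correlation matrix with tip labels as dimnames.
#' @export
correlation_matrix <- function(tree, tol = 1e-8) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths: run grafen_branch_lengths() first",
         call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (max(depths) - min(depths) > tol * max(max(depths), 1)) {
    stop("tree is not ultrametric: run grafen_branch_lengths() first",
         call. = FALSE)
  }
  ape::vcv(tree, corr = TRUE)
}

#' Write a phylogenetic correlation matrix as labelled CSV
#' @param A Correlation matrix from [correlation_matrix()].
#' @param path Output path.
#' @export
write_correlation_csv <- function(A, path) {
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
}
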