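## Neighbor-joining (Saitou-Nei) with the canonical Q-criterion. Written
## in-package because the toolkit's contract pins down determinism: ties in
## Q are broken by the lowest (row, column) index pair in the current node
## ordering (original taxon order first, joined nodes appended), and
## negative branch lengths are clamped to zero with a warning. ape::nj
## serves as an independent cross-check in the tests, not as the
## implementation.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i,j) = (r - 2) d(i,j) - R(i) - R(j)`, attach with the usual branch
#' length split, and reduce the matrix, finishing with the three-point
#' formulas when three nodes remain. Deterministic for fixed input.
#'
#' @param d Symmetric numeric matrix with zero diagonal and taxa dimnames
#'   (as from [pairwise_distance()]); at least three taxa, no NaN.
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be a square matrix")
  if (any(!is.finite(d))) abort("distance matrix contains NaN/Inf entries")
  if (max(abs(d - t(d))) > 1e-9) abort("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 3) abort("neighbor-joining needs at least three taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ## each active node carries a newick subtree string
  node_str <- as.list(labels)
  D <- d
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.12g", x)
  }
  while (length(node_str) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    ## lowest (row, col) pair among minima, row-major
    qmin <- min(Q)
    hits <- which(Q == qmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    new_str <- sprintf("(%s:%s,%s:%s)",
                       node_str[[i]], fmt(li), node_str[[j]], fmt(lj))
    others <- setdiff(seq_len(r), c(i, j))
    new_d <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], new_d),
               c(new_d, 0))
    node_str <- c(node_str[others], list(new_str))
  }
  ## three-point formulas for the final star resolution
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    node_str[[1]], fmt(x1),
                    node_str[[2]], fmt(x2),
                    node_str[[3]], fmt(x3))
  if (clamped) warn("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = newick)
}
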