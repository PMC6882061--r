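## Nonparametric bootstrap over the NJ builder, with partition-aware
## column resampling, and the unrooted-bipartition machinery it shares
## with the monophyly test.

#' Internal bipartitions of an unrooted tree
#'
#' One entry per internal edge: the taxon set on the side of the edge not
#' containing the alphabetically first tip (a canonical orientation, so
#' keys compare across trees). Trivial splits (single tip or all-but-one)
#' are excluded.
#'
#' @param tree `ape::phylo` object.
#' @return Character vector of canonical split keys (taxa sorted, joined
#'   with `|`).
#' @export
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  ## accumulate tip sets below each internal node (postorder)
  ord <- ape::reorder.phylo(tree, "postorder")
  nnode <- n + tree$Nnode
  below <- vector("list", nnode)
  for (tip in seq_len(n)) below[[tip]] <- tree$tip.label[tip]
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next # tip edge, trivial split
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement — within each partition
#' when given a supermatrix, so every resample keeps each gene and codon
#' position's column count — rebuilds a tree per replicate with
#' `tree_builder`, and scores each internal bipartition of the reference
#' tree by the fraction of replicate trees containing it.
#'
#' @param x A `supermatrix` or an alignment (tibble or named character
#'   vector).
#' @param n_replicates Number of bootstrap replicates (at least 1).
#' @param seed Integer seed; recorded in the result.
#' @param tree_builder Function alignment -> `phylo`; defaults to NJ on
#'   JC69 distances.
#' @return List of class `mlst_bootstrap`: `tree` (reference tree, node
#'   labels carrying supports), `support` (tibble `split`, `support`),
#'   `n_replicates`, `seed`.
#' @export
bootstrap_support <- function(x, n_replicates = 100, seed = 1,
                              tree_builder = NULL) {
  if (n_replicates < 1) abort("n_replicates must be at least 1")
  if (is.null(tree_builder)) {
    tree_builder <- function(aln) nj_tree(pairwise_distance(aln, "JC69"))
  }
  if (inherits(x, "supermatrix")) {
    seqs <- x$seqs
    groups <- split(x$partition$column,
                    paste(x$partition$locus, x$partition$codon_pos))
  } else {
    seqs <- .as_alignment(x)
    groups <- list(seq_len(nchar(seqs[1])))
  }
  chars <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  rebuild <- function(cols) {
    aln <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                          collapse = ""), names(seqs))
    tree_builder(aln)
  }
  ref_tree <- rebuild(seq_len(ncol(chars)))
  ref_splits <- tree_bipartitions(ref_tree)
  counts <- setNames(numeric(length(ref_splits)), ref_splits)
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      rep_splits <- tree_bipartitions(suppressWarnings(rebuild(cols)))
      hit <- ref_splits %in% rep_splits
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- tibble(split = ref_splits,
                    support = unname(counts) / n_replicates)
  ## annotate node labels on the reference tree
  tree <- ref_tree
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  ord <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (tip in seq_len(n)) below[[tip]] <- tree$tip.label[tip]
  for (e in seq_len(nrow(ord$edge))) {
    below[[ord$edge[e, 1]]] <- c(below[[ord$edge[e, 1]]],
                                 below[[ord$edge[e, 2]]])
  }
  labs <- rep("", tree$Nnode)
  for (node in (n + 1):(n + tree$Nnode)) {
    side <- below[[node]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% ref_splits) {
      labs[node - n] <- sprintf("%.3g", counts[[key]] / n_replicates)
    }
  }
  tree$node.label <- labs
  structure(list(tree = tree, support = support,
                 n_replicates = n_replicates, seed = seed),
            class = "mlst_bootstrap")
}

#' @exportS3Method generics::tidy
tidy.mlst_bootstrap <- function(x, ...) x$support

#' @export
print.mlst_bootstrap <- function(x, ...) {
  cat(sprintf(
    "NJ bootstrap: %d replicates (seed %d), %d internal splits, median support %.2f\n",
    x$n_replicates, x$seed, nrow(x$support),
    stats::median(x$support$support)))
  invisible(x)
}
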