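## Unrooted monophyly: a taxon set is monophyletic iff some internal edge's
## bipartition separates exactly that set from the rest.

#' Test a clade for (unrooted) monophyly
#'
#' @param tree `ape::phylo` tree.
#' @param members Character vector of tip labels; must be a strict subset
#'   of the tree's taxa with at least two members (singletons and the full
#'   taxon set leave unrooted monophyly undefined).
#' @return `TRUE` iff some internal edge separates exactly `members` from
#'   the remaining taxa.
#' @export
check_monophyly <- function(tree, members) {
  tips <- tree$tip.label
  unknown <- setdiff(members, tips)
  if (length(unknown) > 0) {
    abort(paste0("clade members not in tree: ",
                 paste(unknown, collapse = ", ")))
  }
  members <- unique(members)
  if (length(members) < 2 || length(members) >= length(tips)) {
    abort("monophyly is undefined for singleton or full-taxa clades")
  }
  ref <- sort(tips)[1]
  side <- if (ref %in% members) setdiff(tips, members) else members
  key <- paste(sort(side), collapse = "|")
  key %in% tree_bipartitions(tree)
}

#' Monophyly report for a set of clade definitions
#'
#' @param tree `ape::phylo` tree.
#' @param clades Named list of tip-label vectors (e.g. the scheme's strain
#'   groups A/C/E).
#' @return Tibble `clade`, `size`, `monophyletic`.
#' @export
monophyly_report <- function(tree, clades) {
  stopifnot(is.list(clades), !is.null(names(clades)))
  bind_rows(lapply(names(clades), function(nm) {
    tibble(clade = nm, size = length(clades[[nm]]),
           monophyletic = check_monophyly(tree, clades[[nm]]))
  }))
}
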