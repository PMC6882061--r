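# Independent oracles used across the suite. Everything here is written
# from first principles (own IUPAC table, closed-form transition
# probabilities, exhaustive enumeration) so it never shares a code path
# with the implementation it checks.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N", I = "I")

oracle_revcomp <- function(s) {
  paste(rev(unname(ORACLE_COMP[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_expand <- function(s) {
  sets <- ORACLE_IUPAC[strsplit(s, "")[[1]]]
  out <- ""
  for (set in sets) out <- as.vector(outer(out, set, paste0))
  sort(out)
}

# full site scan by per-position set membership; both strands, 1-based
oracle_scan <- function(primer, template, max_mm = 0, tail_exact = 3) {
  scan_pattern <- function(pattern, tail_at_right) {
    pc <- strsplit(pattern, "")[[1]]
    tc <- strsplit(template, "")[[1]]
    m <- length(pc); n <- length(tc)
    hits <- list()
    if (n < m) return(hits)
    for (o in seq_len(n - m + 1)) {
      mism <- !mapply(function(p, w) w %in% ORACLE_IUPAC[[p]],
                      pc, tc[o:(o + m - 1)])
      tail_idx <- if (tail_at_right) (m - tail_exact + 1):m
                  else seq_len(tail_exact)
      if (sum(mism) <= max_mm && !any(mism[tail_idx])) {
        hits[[length(hits) + 1]] <- c(start = o, end = o + m - 1,
                                      mm = sum(mism))
      }
    }
    hits
  }
  plus <- scan_pattern(primer, tail_at_right = TRUE)
  minus <- scan_pattern(oracle_revcomp(primer), tail_at_right = FALSE)
  rbind(
    if (length(plus)) cbind(do.call(rbind, plus), strand = 1) else NULL,
    if (length(minus)) cbind(do.call(rbind, minus), strand = -1) else NULL
  )
}

# exhaustive strain-set decompositions: all unordered k-multisets of
# complete profiles whose per-locus union equals the observed sets
oracle_decompositions <- function(sets, k) {
  loci <- names(sets)
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  cands <- lapply(seq_len(nrow(grid)), function(i) {
    p <- unlist(grid[i, ]); names(p) <- loci; p
  })
  n <- length(cands)
  picks <- utils::combn(n + k - 1, k, simplify = FALSE)
  picks <- unique(lapply(picks, function(v) sort(v - seq_len(k) + 1)))
  keep <- Filter(function(ix) {
    all(vapply(loci, function(l) {
      setequal(vapply(cands[ix], function(p) as.numeric(p[[l]]),
                      numeric(1)), sets[[l]])
    }, logical(1)))
  }, picks)
  lapply(keep, function(ix) cands[ix])
}

oracle_decomp_label <- function(profiles) {
  keys <- vapply(profiles, function(p) {
    p <- p[order(names(p))]
    paste(paste0(names(p), ":", p), collapse = ",")
  }, character(1))
  paste(sort(keys), collapse = " | ")
}

# closed-form K80 transition matrix (JC69 at kappa = 1), branch length in
# expected substitutions per site
oracle_k80_P <- function(t, kappa = 1) {
  b <- 1 / (kappa + 2)
  e1 <- exp(-4 * b * t)
  e2 <- exp(-2 * (kappa + 1) * b * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2   # transition (A<->G, C<->T)
  tv <- 0.25 - 0.25 * e1              # each transversion
  P <- matrix(tv, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  diag(P) <- same
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- ts
  P
}

# exhaustive likelihood: sum over all internal-node state assignments
oracle_loglik <- function(tree, aln, kappa = 1) {
  bases <- c("A", "C", "G", "T")
  chars <- do.call(rbind, strsplit(unname(aln[tree$tip.label]), ""))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  Ps <- lapply(tree$edge.length, oracle_k80_P, kappa = kappa)
  total <- 0
  for (site in seq_len(ncol(chars))) {
    lik <- 0
    states <- rep(1L, n_int)
    repeat {
      full <- integer(n_tip + n_int)
      full[seq_len(n_tip)] <- match(chars[, site], bases)
      full[n_tip + seq_len(n_int)] <- states
      pr <- 0.25 # root state prior
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * Ps[[e]][full[tree$edge[e, 1]], full[tree$edge[e, 2]]]
      }
      lik <- lik + pr
      # odometer over internal states
      i <- 1L
      while (i <= n_int && states[i] == 4L) { states[i] <- 1L; i <- i + 1L }
      if (i > n_int) break
      states[i] <- states[i] + 1L
    }
    total <- total + log(lik)
  }
  total
}

# ordinary-least-squares fit of a distance matrix on a fixed topology;
# returns the residual sum of squares
oracle_ls_ss <- function(topology, d) {
  tr <- ape::unroot(topology)
  taxa <- rownames(d)
  n <- length(taxa)
  n_edge <- nrow(tr$edge)
  # tip set below each edge's child
  ord <- ape::reorder.phylo(tr, "postorder")
  below <- vector("list", n + tr$Nnode)
  for (tip in seq_len(n)) below[[tip]] <- tr$tip.label[tip]
  for (e in seq_len(nrow(ord$edge))) {
    below[[ord$edge[e, 1]]] <- c(below[[ord$edge[e, 1]]],
                                 below[[ord$edge[e, 2]]])
  }
  pairs <- t(utils::combn(taxa, 2))
  X <- matrix(0, nrow(pairs), n_edge)
  for (e in seq_len(n_edge)) {
    side <- below[[tr$edge[e, 2]]]
    X[, e] <- xor(pairs[, 1] %in% side, pairs[, 2] %in% side)
  }
  y <- d[pairs]
  fit <- qr.solve(X, y)
  sum((X %*% fit - y)^2)
}

# all 15 unrooted 5-taxon topologies over the given labels
oracle_all_topologies_5 <- function(labels) {
  stopifnot(length(labels) == 5)
  quartets <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  out <- list()
  for (q in quartets) {
    base <- sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);",
                    labels[q[1]], labels[q[2]], labels[q[3]], labels[q[4]])
    tr <- ape::unroot(ape::read.tree(text = base))
    for (e in seq_len(nrow(tr$edge))) {
      tr5 <- ape::bind.tree(tr, ape::read.tree(text = sprintf("(%s:1);",
                                                              labels[5])),
                            where = tr$edge[e, 2], position = 0.5)
      out[[length(out) + 1]] <- ape::unroot(tr5)
    }
  }
  # deduplicate by unrooted split sets
  keys <- vapply(out, function(x) {
    paste(sort(tree_bipartitions(x)), collapse = ";")
  }, character(1))
  out[!duplicated(keys)]
}

random_degenerate_string <- function(len, max_fold = 4) {
  syms <- names(ORACLE_IUPAC)
  sizes <- vapply(ORACLE_IUPAC, length, integer(1))
  pool <- syms[sizes <= max_fold & syms != "I"]
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

random_additive_matrix <- function(n_taxa = 5, seed = 1) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  })
  list(tree = ape::unroot(tr), d = ape::cophenetic.phylo(tr))
}
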