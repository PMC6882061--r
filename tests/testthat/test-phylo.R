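# Supermatrix construction, distances, NJ against brute-force topology
# search, pruning likelihood against exhaustive state summation, AIC
# selection, bootstrap supports, and monophyly.

make_aln <- function(taxa, len, seed) {
  withr::with_seed(seed, {
    setNames(vapply(taxa, function(t) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1)), taxa)
  })
}

test_that("concatenation fixes column order, widths and codon positions", {
  taxa <- c("s1", "s2", "s3")
  lens <- c(gyrB = 736, groEL = 476, sufB = 451, `EF-G` = 482)
  alns <- lapply(seq_along(lens), function(i) {
    make_aln(taxa, lens[i], seed = 70 + i)
  })
  names(alns) <- names(lens)
  sm <- concatenate_loci(alns)
  expect_equal(nchar(sm$seqs[[1]]), 2145)
  expect_equal(nrow(sm$partition), 2145)
  # slicing recovers the inputs byte-exactly
  for (l in names(lens)) {
    expect_identical(slice_supermatrix(sm, l), alns[[l]])
  }
  # frame-1 locus of length 6 cycles codon positions 1,2,3,1,2,3
  one <- concatenate_loci(list(x = make_aln(taxa, 6, 99)))
  expect_equal(one$partition$codon_pos, c(1, 2, 3, 1, 2, 3))
  # a fragment starting at gene coordinate 882 opens in codon position 3
  off <- concatenate_loci(list(x = make_aln(taxa, 6, 99)),
                          frame_offsets = c(x = 882))
  expect_equal(off$partition$codon_pos[1], 3)
  # asymmetric taxa rejected unless padding is requested
  alns_bad <- alns
  alns_bad$gyrB <- alns_bad$gyrB[-1]
  expect_error(concatenate_loci(alns_bad), "s1")
  sm_pad <- concatenate_loci(alns_bad, pad_missing = TRUE)
  expect_equal(substr(sm_pad$seqs[["s1"]], 1, 5), "-----")
})

test_that("p and JC69 distances follow their closed forms", {
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 30), strrep("A", 70))
  aln <- c(x = a, y = b)
  expect_equal(pairwise_distance(aln, "p")["x", "y"], 0.3)
  expect_equal(pairwise_distance(aln, "JC69")["x", "y"],
               -0.75 * log(1 - 0.4))
  expect_equal(pairwise_distance(c(x = a, y = a), "JC69")["x", "y"], 0)
  # symmetry on simulated alignments, and agreement with ape::dist.dna
  tr4 <- ape::read.tree(text = "((t1:0.1,t2:0.15):0.05,(t3:0.1,t4:0.2):0.05);")
  aln_r <- evolve_sequences(tr4, 300, seed = 73)
  d <- pairwise_distance(aln_r, "JC69")
  expect_equal(d, t(d))
  dd <- ape::dist.dna(ape::as.DNAbin(do.call(rbind,
                                             strsplit(tolower(aln_r), ""))),
                      model = "JC69")
  expect_equal(as.numeric(as.dist(d)), as.numeric(dd), tolerance = 1e-10)
  # saturated pairs flagged, no NaN
  sat <- c(x = strrep("A", 40), y = strrep("C", 40), z = strrep("A", 40))
  expect_warning(ds <- pairwise_distance(sat, "JC69"), "saturated")
  expect_true(attr(ds, "saturated")["x", "y"])
  expect_false(any(is.nan(ds)))
  # a pair with zero comparable sites is an error naming the pair
  gappy <- c(x = "AC--", y = "--GT", z = "ACGT")
  expect_error(pairwise_distance(gappy, "p"), "'x' and 'y'")
})

test_that("NJ recovers known trees from additive distances", {
  # 4-taxon round trip with exact branch lengths
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.07);")
  d <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  # n = 3: unique star with three-point branch lengths
  d3 <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj3 <- nj_tree(d3)
  bl <- setNames(nj3$edge.length, nj3$tip.label[nj3$edge[, 2]])
  expect_equal(bl[["a"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(bl[["c"]], (0.4 + 0.5 - 0.3) / 2)
  # malformed input is rejected
  expect_error(nj_tree(d3[1:2, 1:2]), "three")
  d_bad <- d3; d_bad[1, 2] <- 9
  expect_error(nj_tree(d_bad), "symmetric")
})

test_that("NJ equals exhaustive least-squares search on 5-taxon additive
           matrices and agrees with ape::nj", {
  topos <- oracle_all_topologies_5(paste0("t", 1:5))
  expect_length(topos, 15)
  for (seed in 1:10) {
    ad <- random_additive_matrix(5, seed = seed)
    nj <- nj_tree(ad$d)
    # oracle: topology with zero least-squares residual
    ss <- vapply(topos, oracle_ls_ss, numeric(1), d = ad$d)
    best <- topos[[which.min(ss)]]
    expect_lt(min(ss), 1e-12)
    expect_equal(ape::dist.topo(nj, best), setNames(0, "PH85"),
                 ignore_attr = TRUE)
    # independent implementation cross-check
    expect_equal(ape::dist.topo(nj, ape::unroot(ape::nj(ad$d))),
                 setNames(0, "PH85"), ignore_attr = TRUE)
  }
})

test_that("pruning likelihood equals exhaustive state summation", {
  withr::with_seed(79, {
    for (rep in 1:10) {
      n_taxa <- sample(3:4, 1)
      n_sites <- sample(2:6, 1)
      tr <- ape::rtree(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
      tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.8)
      aln <- evolve_sequences(tr, n_sites, seed = sample.int(1e6, 1))
      for (kappa in c(1, 3)) {
        model <- if (kappa == 1) subst_model("JC69")
                 else subst_model("K80", kappa = kappa)
        got <- tree_log_likelihood(tr, aln, model)
        want <- oracle_loglik(tr, aln, kappa = kappa)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  })
})

test_that("likelihood is invariant under re-rooting and has the JC
           zero-branch limit", {
  tr <- ape::read.tree(
    text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.07);")
  aln <- evolve_sequences(tr, 100, seed = 83)
  base <- tree_log_likelihood(tr, aln)
  for (og in c("A", "C", "D")) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                          resolve.root = TRUE)
    expect_equal(tree_log_likelihood(rerooted, aln), base,
                 tolerance = 1e-9)
  }
  # all branches zero, identical sequences: lnL = sites * log(1/4)
  tr0 <- tr
  tr0$edge.length[] <- 0
  aln0 <- setNames(rep(strrep("ACGT", 10), 4), tr$tip.label)
  expect_equal(tree_log_likelihood(tr0, aln0), 40 * log(0.25))
  expect_error(tree_log_likelihood(tr, aln[c(2, 1, 3, 4)][-1]), "differ")
})

test_that("AIC selection nests correctly and reports a deterministic
           table", {
  sim <- simulate_tree(6, seed = 89)
  aln <- evolve_sequences(sim$tree, 400, seed = 89)
  tree <- nj_tree(pairwise_distance(aln, "JC69"))
  tab1 <- aic_select(aln, tree)
  tab2 <- aic_select(aln, tree)
  expect_identical(tidy(tab1), tidy(tab2))
  lnl <- setNames(tab1$lnL, tab1$model)
  expect_gte(lnl[["K80"]], lnl[["JC69"]]) # nested models
  expect_equal(tab1$k,
               unname(c(JC69 = 0L, K80 = 1L, HKY85 = 4L)[tab1$model]))
  expect_equal(tab1$AIC, 2 * tab1$k - 2 * tab1$lnL)
  expect_equal(tab1$dAIC[1], 0)
})

test_that("bootstrap supports live in [0,1], are taxon-order invariant,
           and find a strongly supported split", {
  sim <- simulate_tree(6, c(A = 3), seed = 97, stem_length = 0.5)
  aln <- evolve_sequences(sim$tree, 500, seed = 97)
  bs <- bootstrap_support(aln, n_replicates = 60, seed = 5)
  expect_true(all(bs$support$support >= 0 & bs$support$support <= 1))
  bs2 <- bootstrap_support(aln[rev(seq_along(aln))], n_replicates = 60,
                           seed = 5)
  common <- intersect(bs$support$split, bs2$support$split)
  expect_true(length(common) > 0)
  s1 <- setNames(bs$support$support, bs$support$split)[common]
  s2 <- setNames(bs2$support$support, bs2$support$split)[common]
  expect_equal(s1, s2)
  # the planted clade's split is strongly supported (canonical key: the
  # side not containing the alphabetically first tip)
  tips <- bs$tree$tip.label
  side <- sim$clades$A
  if (sort(tips)[1] %in% side) side <- setdiff(tips, side)
  key <- paste(sort(side), collapse = "|")
  expect_gt(bs$support$support[bs$support$split == key], 0.95)
})

test_that("unrooted monophyly matches a rooted traversal oracle", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_true(check_monophyly(tr, c("A1", "A2")))
  expect_false(check_monophyly(tr, c("A1", "B1")))
  expect_error(check_monophyly(tr, "A1"), "undefined")
  expect_error(check_monophyly(tr, c("A1", "A2", "B1", "B2")), "undefined")
  expect_error(check_monophyly(tr, c("A1", "Z9")), "Z9")
  withr::with_seed(101, {
    for (rep in 1:10) {
      tr_r <- ape::rtree(8, tip.label = paste0("t", 1:8))
      members <- sample(tr_r$tip.label, sample(2:6, 1))
      out <- setdiff(tr_r$tip.label, members)[1]
      rooted <- ape::root(ape::unroot(tr_r), outgroup = out,
                          resolve.root = TRUE)
      want <- ape::is.monophyletic(rooted, members)
      expect_equal(check_monophyly(tr_r, members), want)
    }
  })
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  sim <- simulate_tree(7, c(A = 3), seed = 103)
  # clamping warnings are expected on short resampled alignments
  bs <- suppressWarnings(
    bootstrap_support(evolve_sequences(sim$tree, 200, seed = 103),
                      n_replicates = 20, seed = 7))
  p <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(bs$tree, p)
  back <- ape::read.tree(p)
  expect_equal(ape::dist.topo(back, bs$tree), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(bs$tree$edge.length),
               tolerance = 1e-6)
  expect_setequal(setdiff(back$node.label, ""),
                  setdiff(bs$tree$node.label, ""))
})
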