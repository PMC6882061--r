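## Synthetic data with known ground truth for every other module: trees
## with planted clades, sequence evolution under JC69/K80, templates with
## planted primer binding sites, and co-infected individuals with known
## strain assignments and titers. All generators take an explicit seed and
## are bit-reproducible given (arguments, seed).

#' Simulate a tree with planted monophyletic clades
#'
#' Builds a random backbone over the non-clade taxa and one placeholder
#' per clade, then replaces each placeholder by a random subtree of the
#' clade's members attached through a long stem — so every planted clade
#' is monophyletic by construction. Background divergence and stem lengths
#' default to the moderate-divergence regime the package's clade-recovery
#' checks assume (backbone and within-clade branches a few percent of
#' substitutions per site, stems an order of magnitude longer).
#'
#' @param n_taxa Total number of taxa (at least 4).
#' @param clade_spec Named integer vector of clade sizes, e.g.
#'   `c(A = 5, C = 3, E = 3)`; must sum to at most `n_taxa`. Clade members
#'   are labelled `<clade><i>`, background taxa `bg<i>`.
#' @param seed Integer seed.
#' @param stem_length Stem branch length attaching each clade.
#' @param branch_scale Mean length of backbone and within-clade branches.
#' @return List with `tree` (`phylo`) and `clades` (named list of member
#'   labels).
#' @export
simulate_tree <- function(n_taxa, clade_spec = integer(0), seed = 1,
                          stem_length = 0.3, branch_scale = 0.03) {
  if (n_taxa < 4) abort("n_taxa must be at least 4")
  if (sum(clade_spec) > n_taxa) {
    abort("clade sizes exceed n_taxa")
  }
  if (length(clade_spec) > 0 && is.null(names(clade_spec))) {
    abort("clade_spec must be named")
  }
  n_bg <- n_taxa - sum(clade_spec)
  clades <- lapply(names(clade_spec), function(nm) {
    paste0(nm, seq_len(clade_spec[[nm]]))
  })
  names(clades) <- names(clade_spec)
  withr::with_seed(seed, {
    units <- c(paste0("bg", seq_len(n_bg)),
               paste0(".clade_", names(clade_spec)))
    if (length(units) < 2) abort("need at least two backbone units")
    backbone <- if (length(units) == 2) {
      ape::read.tree(text = sprintf("(%s:1,%s:1);", units[1], units[2]))
    } else {
      ape::rtree(length(units), tip.label = sample(units))
    }
    backbone$edge.length <- stats::rexp(nrow(backbone$edge),
                                        rate = 1 / branch_scale)
    tree <- backbone
    for (nm in names(clade_spec)) {
      size <- clade_spec[[nm]]
      sub <- if (size == 1) {
        NULL
      } else if (size == 2) {
        ape::read.tree(text = sprintf("(%s1:%g,%s2:%g);", nm,
                                      branch_scale, nm, branch_scale))
      } else {
        s <- ape::rtree(size, tip.label = sample(clades[[nm]]))
        s$edge.length <- stats::rexp(nrow(s$edge), rate = 1 / branch_scale)
        s
      }
      at <- which(tree$tip.label == paste0(".clade_", nm))
      if (is.null(sub)) {
        tree$tip.label[at] <- clades[[nm]][1]
        tree$edge.length[tree$edge[, 2] == at] <-
          tree$edge.length[tree$edge[, 2] == at] + stem_length
      } else {
        sub$root.edge <- stem_length
        tree <- ape::bind.tree(tree, sub, where = at)
      }
    }
  })
  list(tree = tree, clades = clades)
}

#' Evolve sequences along a tree
#'
#' Draws a root sequence from the model's stationary frequencies and
#' propagates states down every branch with the model's transition
#' probabilities. No indels, no rate heterogeneity among sites.
#'
#' @param tree `ape::phylo` tree with branch lengths (substitutions/site).
#' @param length Number of sites.
#' @param model [subst_model()] object.
#' @param seed Integer seed.
#' @return Named character vector alignment over the tree's tips.
#' @export
evolve_sequences <- function(tree, length, model = subst_model("JC69"),
                             seed = 1) {
  if (length < 1) abort("length must be positive")
  eig <- .model_eigen(model)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  ## preorder = reversed postorder edge list
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  withr::with_seed(seed, {
    states <- matrix(NA_integer_, n_tip + tree$Nnode, length)
    states[root, ] <- sample.int(4, length, replace = TRUE,
                                 prob = model$freqs)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; ch <- edges[e, 2]
      P <- .transition_matrix(eig, elen[e])
      child <- integer(length)
      for (s in 1:4) {
        idx <- which(states[par, ] == s)
        if (length(idx) > 0) {
          child[idx] <- sample.int(4, length(idx), replace = TRUE,
                                   prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
  })
  aln <- apply(states[seq_len(n_tip), , drop = FALSE], 1, function(row) {
    paste(.bases[row], collapse = "")
  })
  setNames(aln, tree$tip.label)
}

#' Build a template with planted primer binding sites
#'
#' Random A/C/G/T background of `gene_length` bases carrying one concrete
#' realization of the pair's forward primer starting at `amp_start` and
#' the reverse complement of a concrete realization of the reverse primer
#' ending at `amp_end` — so in-silico PCR recovers exactly one product
#' spanning the amplified range. Backgrounds with spurious binding sites
#' are rejected and redrawn a bounded number of times.
#'
#' @param pair One row of [scheme_pairs()] (needs `fwd_seq`, `rev_seq`,
#'   `amp_start`, `amp_end`).
#' @param gene_length Template length; at least `amp_end`.
#' @param seed Integer seed.
#' @param max_mismatches Spurious-site tolerance used during rejection.
#' @param max_tries Rejection budget before giving up.
#' @return Template string of length `gene_length`.
#' @export
plant_primer_sites <- function(pair, gene_length = pair$gene_length,
                               seed = 1, max_mismatches = 0L,
                               max_tries = 20L) {
  if (gene_length < pair$amp_end) {
    abort("gene_length must reach at least amp_end")
  }
  fwd_len <- nchar(pair$fwd_seq)
  rev_len <- nchar(pair$rev_seq)
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      bg <- paste(sample(.bases, gene_length, replace = TRUE),
                  collapse = "")
      fwd_real <- sample(expand_degenerate(pair$fwd_seq), 1)
      rev_real <- sample(expand_degenerate(pair$rev_seq), 1)
      tmpl <- bg
      substr(tmpl, pair$amp_start, pair$amp_start + fwd_len - 1L) <- fwd_real
      substr(tmpl, pair$amp_end - rev_len + 1L, pair$amp_end) <-
        revcomp(rev_real)
      f_sites <- find_binding_sites(pair$fwd_seq, tmpl, max_mismatches)
      r_sites <- find_binding_sites(pair$rev_seq, tmpl, max_mismatches)
      f_ok <- nrow(filter(f_sites, .data$strand == "+")) == 1 &&
        filter(f_sites, .data$strand == "+")$start == pair$amp_start
      r_minus <- filter(r_sites, .data$strand == "-")
      r_ok <- nrow(r_minus) == 1 && r_minus$end == pair$amp_end
      if (f_ok && r_ok) return(tmpl)
    }
  })
  abort(sprintf(
    "no clean template in %d tries; a longer template may help", max_tries))
}

#' Simulate a co-infection dataset with known truth
#'
#' Plants `k` strains (strain `r` carries allele `r` at every locus),
#' assigns an `anchor_fraction` of individuals a single strain (round
#' robin over strains) and the rest all `k` strains, and draws per-allele
#' titers log-normally around strain-specific means separated by
#' `titer_ratio`. The defaults emulate a two-strain system at a 10:1
#' density ratio across 20 individuals — the high/low-density co-infection
#' regime that motivates titer-based assignment.
#'
#' @param k Number of strains (at least 2).
#' @param n_individuals Number of sampled individuals.
#' @param loci Character vector of locus names.
#' @param anchor_fraction Fraction of individuals that are singly infected.
#' @param titer_ratio Density ratio between consecutive strains.
#' @param titer_sd Log-scale (natural log) standard deviation of titers.
#' @param base_titer Mean titer of the lowest-density strain.
#' @param seed Integer seed.
#' @return List with `observations` (tibble `individual_id`, `locus`,
#'   `allele_id`), `titers` (same keys plus `titer`, rows only for
#'   co-infected individuals), and `truth` (list: `profiles` tibble,
#'   `infections` tibble, `strain_of_allele` map).
#' @export
simulate_coinfection <- function(k = 2, n_individuals = 20,
                                 loci = c("gyrB", "groEL", "sufB", "EF-G"),
                                 anchor_fraction = 0.3, titer_ratio = 10,
                                 titer_sd = 0.2, base_titer = 10,
                                 seed = 1) {
  if (k < 2) abort("k must be at least 2")
  profiles <- tidyr::expand_grid(strain = seq_len(k), locus = loci) %>%
    mutate(allele_id = .data$strain)
  strain_means <- base_titer * titer_ratio^(rev(seq_len(k)) - 1L)
  withr::with_seed(seed, {
    n_single <- round(anchor_fraction * n_individuals)
    status <- c(rep("single", n_single),
                rep("multi", n_individuals - n_single))
    single_strain <- rep(seq_len(k), length.out = n_single)
    obs <- list(); titers <- list(); infections <- list()
    for (i in seq_len(n_individuals)) {
      ind <- sprintf("ind%02d", i)
      if (status[i] == "single") {
        strains <- single_strain[i]
      } else {
        strains <- seq_len(k)
      }
      infections[[i]] <- tibble(individual_id = ind,
                                strains = list(strains),
                                class = status[i])
      obs[[i]] <- tidyr::expand_grid(locus = loci, strain = strains) %>%
        mutate(individual_id = ind, allele_id = .data$strain) %>%
        select("individual_id", "locus", "allele_id")
      if (length(strains) > 1) {
        titers[[i]] <- tidyr::expand_grid(locus = loci, strain = strains) %>%
          mutate(individual_id = ind, allele_id = .data$strain,
                 titer = rlnorm(dplyr::n(),
                                meanlog = log(strain_means[.data$strain]),
                                sdlog = titer_sd)) %>%
          select("individual_id", "locus", "allele_id", "titer")
      }
    }
  })
  list(observations = bind_rows(obs),
       titers = bind_rows(titers),
       truth = list(profiles = profiles,
                    infections = bind_rows(infections),
                    strain_of_allele = setNames(seq_len(k), seq_len(k))))
}
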