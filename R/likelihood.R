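## Felsenstein pruning likelihood under JC69 / K80 / HKY85, and AIC model
## selection on a fixed tree. HKY85 nests the other two (kappa = 1 gives
## F81; equal frequencies give K80; both give JC69), so one rate-matrix
## builder serves all three. Transition probabilities come from the
## spectral decomposition of the frequency-symmetrized rate matrix, with
## the matrix scaled so branch lengths are expected substitutions per site.

.bases <- c("A", "C", "G", "T")

#' Construct a substitution model
#'
#' @param name `"JC69"`, `"K80"` or `"HKY85"`.
#' @param kappa Transition/transversion rate ratio (K80, HKY85); 1 under
#'   JC69.
#' @param freqs Base frequencies in A, C, G, T order summing to 1 (HKY85);
#'   uniform otherwise.
#' @return Object of class `subst_model` with elements `name`, `kappa`,
#'   `freqs`, `n_free` (free-parameter count: 0 / 1 / 4).
#' @export
subst_model <- function(name = c("JC69", "K80", "HKY85"), kappa = 1,
                        freqs = rep(0.25, 4)) {
  name <- match.arg(name)
  if (kappa <= 0) abort("kappa must be positive")
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4 || any(freqs <= 0) ||
      abs(sum(freqs) - 1) > 1e-8) {
    abort("freqs must be four positive values summing to 1")
  }
  if (name == "JC69") { kappa <- 1; freqs <- rep(0.25, 4) }
  if (name == "K80") freqs <- rep(0.25, 4)
  n_free <- switch(name, JC69 = 0L, K80 = 1L, HKY85 = 4L)
  structure(list(name = name, kappa = kappa,
                 freqs = setNames(freqs, .bases), n_free = n_free),
            class = "subst_model")
}

## rate matrix scaled to one expected substitution per unit branch length,
## plus its spectral decomposition for fast P(t)
.model_eigen <- function(model) {
  pi_ <- unname(model$freqs)
  kappa <- model$kappa
  is_transition <- matrix(FALSE, 4, 4)
  is_transition[1, 3] <- is_transition[3, 1] <- TRUE # A <-> G
  is_transition[2, 4] <- is_transition[4, 2] <- TRUE # C <-> T
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- ifelse(is_transition[i, j], kappa, 1) * pi_[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_ * diag(Q))
  Q <- Q / mu
  ## symmetrize: B = D^(1/2) Q D^(-1/2) with D = diag(pi)
  sp <- sqrt(pi_)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = eig$values,
       right = diag(1 / sp) %*% eig$vectors,
       left = t(eig$vectors) %*% diag(sp))
}

## P(t) = right diag(e^(lambda t)) left; rows = from-state
.transition_matrix <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0 # clip tiny negative round-off
  P
}

#' JC69 transition probability (closed form)
#'
#' Probability of observing the same base after branch length `t`:
#' `1/4 + 3/4 exp(-4 t / 3)`; a specific different base has probability
#' `1/4 - 1/4 exp(-4 t / 3)`. Used as an independent check on the general
#' matrix-exponential path.
#'
#' @param t Branch length (expected substitutions per site).
#' @param same Probability of identity (`TRUE`) or of one specific change.
#' @return Probability.
#' @export
jc69_transition <- function(t, same = TRUE) {
  if (same) 0.25 + 0.75 * exp(-4 * t / 3) else 0.25 - 0.25 * exp(-4 * t / 3)
}

## per-site partial likelihood indicators for IUPAC characters: ambiguity
## codes and gaps are missing data (indicator over the allowed set; gap/N
## give a vector of ones)
.tip_partial <- function(ch, codes) {
  allowed <- codes[[ch]]
  if (length(allowed) == 0) allowed <- .bases
  as.numeric(.bases %in% allowed)
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Sums over sites the log of the pruning recursion, with site patterns
#' compressed. Gaps and ambiguity codes are treated as missing data. The
#' likelihood of an unrooted tree is independent of the rooting used for
#' the recursion (the pulley principle), which the tests exercise.
#'
#' @param tree `ape::phylo` tree whose tip labels match the alignment
#'   names; branch lengths in expected substitutions per site.
#' @param alignment Tibble (`id`, `seq`) or named character vector.
#' @param model [subst_model()] object.
#' @return Log-likelihood (single number).
#' @export
tree_log_likelihood <- function(tree, alignment, model = subst_model("JC69")) {
  aln <- .as_alignment(alignment)
  if (!setequal(tree$tip.label, names(aln))) {
    abort("tree tip labels and alignment names differ")
  }
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  chars <- do.call(rbind,
                   strsplit(toupper(unname(aln[tree$tip.label])), "",
                            fixed = TRUE))
  ## site-pattern compression
  pat_key <- apply(chars, 2, paste, collapse = "")
  uniq <- !duplicated(pat_key)
  weights <- as.numeric(table(pat_key)[pat_key[uniq]])
  cols <- which(uniq)
  npat <- length(cols)
  codes <- iupac_codes("universal")
  eig <- .model_eigen(model)
  n_tip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", n_tip + tree$Nnode)
  for (tip in seq_len(n_tip)) {
    partial[[tip]] <- vapply(chars[tip, cols], .tip_partial,
                             numeric(4), codes = codes)
  }
  root <- ord$edge[nrow(ord$edge), 1]
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    P <- .transition_matrix(eig, ord$edge.length[e])
    contrib <- P %*% partial[[ch]]
    partial[[par]] <- if (is.null(partial[[par]])) contrib
                      else partial[[par]] * contrib
  }
  site_lik <- as.numeric(model$freqs %*% partial[[root]])
  sum(weights * log(site_lik))
}

#' AIC model selection on a fixed tree
#'
#' Fits each candidate model on the given tree (topology and branch
#' lengths fixed, shared across models): JC69 has nothing to fit; K80's
#' kappa is optimized by bounded one-dimensional search (and kappa = 1 is
#' always evaluated too, so its likelihood can never fall below JC69's);
#' HKY85 uses empirical base frequencies and optimizes kappa. `AIC = 2k -
#' 2 lnL` counts only substitution-model free parameters (branch lengths
#' are identical across models, so relative AIC is model-driven).
#'
#' @param alignment Tibble (`id`, `seq`) or named character vector.
#' @param tree Fixed `ape::phylo` tree with branch lengths.
#' @param models Subset of `c("JC69", "K80", "HKY85")`.
#' @param kappa_range Search interval for kappa.
#' @return Object of class `mlst_aic`: tibble `model`, `lnL`, `k`, `kappa`,
#'   `AIC`, `dAIC`, sorted by AIC; attribute `best` holds the winning
#'   [subst_model()].
#' @export
aic_select <- function(alignment, tree,
                       models = c("JC69", "K80", "HKY85"),
                       kappa_range = c(0.05, 50)) {
  models <- match.arg(models, several.ok = TRUE)
  aln <- .as_alignment(alignment)
  emp <- table(factor(unlist(strsplit(toupper(unname(aln)), "",
                                      fixed = TRUE)),
                      levels = .bases))
  emp_freqs <- (as.numeric(emp) + 1) / (sum(emp) + 4) # add-one smoothing
  rows <- list()
  fitted <- list()
  for (m in models) {
    if (m == "JC69") {
      mod <- subst_model("JC69")
      lnl <- tree_log_likelihood(tree, aln, mod)
    } else {
      freqs <- if (m == "HKY85") emp_freqs else rep(0.25, 4)
      obj <- function(log_kappa) {
        -tree_log_likelihood(tree, aln,
                             subst_model(m, kappa = exp(log_kappa),
                                         freqs = freqs))
      }
      opt <- optimize(obj, interval = log(kappa_range))
      cand_kappa <- c(exp(opt$minimum), 1)
      lnls <- c(-opt$objective, -obj(0))
      pick <- which.max(lnls)
      mod <- subst_model(m, kappa = cand_kappa[pick], freqs = freqs)
      lnl <- lnls[pick]
    }
    fitted[[m]] <- mod
    rows[[m]] <- tibble(model = m, lnL = lnl, k = mod$n_free,
                        kappa = mod$kappa)
  }
  out <- bind_rows(rows) %>%
    mutate(AIC = 2 * .data$k - 2 * .data$lnL) %>%
    arrange(.data$AIC, .data$model) %>%
    mutate(dAIC = .data$AIC - min(.data$AIC))
  attr(out, "best") <- fitted[[out$model[1]]]
  structure(out, class = c("mlst_aic", class(out)))
}

#' @exportS3Method generics::tidy
tidy.mlst_aic <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.mlst_aic <- function(x, ...) {
  tibble(best_model = x$model[1], best_AIC = x$AIC[1],
         best_lnL = x$lnL[1], n_models = nrow(x))
}

#' @export
autoplot.mlst_aic <- function(object, ...) {
  df <- as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$model,
                                                      .data$dAIC),
                                   y = .data$dAIC)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(Delta * AIC)) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
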