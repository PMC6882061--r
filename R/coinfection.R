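## Co-infection genotype deconvolution. Two complementary strategies from
## the MLST literature on multiply-infected hosts:
##  - allelic intersection analysis: singly-infected individuals anchor
##    profiles; anchored profiles are subtracted from the allele sets of
##    multiply-infected individuals, and uniquely-remaining alleles are
##    assigned to the residual strain. Anything not uniquely resolvable is
##    reported with every consistent decomposition, never guessed.
##  - titer rank consistency: when co-infecting strains sit at different
##    densities (cf. the high/low-density cEina2/cEina3 pair), per-allele
##    qPCR titers rank alleles within each individual and locus; alleles
##    of equal rank across loci form a candidate strain.

## observations tibble -> per-individual named list of sorted allele sets
.obs_sets <- function(observations) {
  stopifnot(all(c("individual_id", "locus", "allele_id") %in%
                  names(observations)))
  split(observations, observations$individual_id) |>
    lapply(function(df) {
      lapply(split(df$allele_id, df$locus), function(a) sort(unique(a)))
    })
}

.profile_key <- function(p) {
  p <- p[order(names(p))]
  paste(paste0(names(p), ":", ifelse(is.na(p), ".", p)), collapse = ",")
}

## all complete profiles over `loci` drawing one allele per locus from sets
.candidate_profiles <- function(sets, loci) {
  grids <- lapply(loci, function(l) sets[[l]])
  names(grids) <- loci
  g <- do.call(tidyr::expand_grid, grids)
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ]))
}

## decompositions: unordered selections (with repetition) of `r` candidate
## profiles such that, together with `fixed` profiles, the per-locus union
## equals the observed sets
.decompositions <- function(sets, loci, r, fixed = list(), cap = 2e5) {
  cands <- .candidate_profiles(sets, loci)
  if (r == 0) {
    covered <- all(vapply(loci, function(l) {
      setequal(unlist(lapply(fixed, `[[`, l)), sets[[l]])
    }, logical(1)))
    return(if (covered) list(list()) else list())
  }
  if (length(cands)^r > cap) return(NULL) # enumeration refused, too large
  idx <- utils::combn(length(cands) + r - 1L, r, simplify = FALSE)
  ## multiset combinations via stars-and-bars on sorted index tuples
  picks <- lapply(idx, function(v) sort(v - seq_len(r) + 1L))
  picks <- unique(picks)
  out <- list()
  for (p in picks) {
    chosen <- cands[p]
    ok <- all(vapply(loci, function(l) {
      setequal(c(unlist(lapply(fixed, `[[`, l)),
                 unlist(lapply(chosen, `[[`, l))), sets[[l]])
    }, logical(1)))
    if (ok) out[[length(out) + 1L]] <- chosen
  }
  out
}

.decomp_label <- function(chosen) {
  paste(sort(vapply(chosen, .profile_key, character(1))), collapse = " | ")
}

#' Resolve co-infections by allelic intersection analysis
#'
#' Singly-infected individuals (at most one allele at every locus) anchor
#' complete or partial allelic profiles. For each multiply-infected
#' individual, anchored profiles consistent with its allele sets are
#' subtracted; at loci where exactly one unexplained allele remains for a
#' single residual strain, that allele is assigned. Observations that are
#' not uniquely resolvable are emitted in the ambiguity report together
#' with every strain-set decomposition consistent with them; observations
#' consistent with no decomposition at all are flagged as conflicting, not
#' dropped. Output is invariant under reordering of the observations.
#'
#' @param observations Tibble with columns `individual_id`, `locus`,
#'   `allele_id`; one row per observed allele (so multiply-infected
#'   individuals have several rows per locus).
#' @return Object of class `mlst_intersection`: a list with `profiles`
#'   (tibble `profile_id`, `source`, `complete`, `locus`, `allele_id`),
#'   `ambiguities` (tibble `individual_id`, `n_strains`,
#'   `n_decompositions`, `decompositions` list-column of label strings),
#'   and `conflicts` (tibble `individual_id`, `reason`).
#' @export
resolve_by_intersection <- function(observations) {
  if (nrow(observations) == 0) abort("at least one observation is required")
  sets <- .obs_sets(observations)
  loci <- sort(unique(observations$locus))
  ## anchors from singly-infected individuals (deduplicated, canonical order)
  singly <- names(sets)[vapply(sets, function(s) {
    all(vapply(s, length, integer(1)) <= 1L)
  }, logical(1))]
  anchors <- list()
  for (ind in sort(singly)) {
    p <- setNames(rep(NA_integer_, length(loci)), loci)
    for (l in names(sets[[ind]])) p[[l]] <- sets[[ind]][[l]]
    anchors[[.profile_key(p)]] <- p
  }
  anchors <- anchors[sort(names(anchors))]
  profiles <- anchors
  sources <- setNames(rep("anchor", length(anchors)), names(anchors))
  ambiguities <- list()
  conflicts <- list()
  multiply <- setdiff(names(sets), singly)
  for (ind in sort(multiply)) {
    s <- sets[[ind]]
    obs_loci <- names(s)
    k <- max(vapply(s, length, integer(1)))
    consistent <- Filter(function(a) {
      all(vapply(obs_loci, function(l) {
        is.na(a[[l]]) || a[[l]] %in% s[[l]]
      }, logical(1)))
    }, anchors)
    n_resid <- k - length(consistent)
    resolved <- FALSE
    if (n_resid == 1L) {
      ## subtract consistent anchors; assign loci with a unique leftover
      inferred <- setNames(rep(NA_integer_, length(loci)), loci)
      ok <- TRUE
      for (l in obs_loci) {
        explained <- unlist(lapply(consistent, `[[`, l))
        left <- setdiff(s[[l]], explained[!is.na(explained)])
        if (length(left) == 1L) {
          inferred[[l]] <- left
        } else if (length(left) > 1L) {
          ok <- FALSE # one residual strain cannot carry two alleles
        } # zero left: residual allele hidden among anchors', stays NA
      }
      if (ok && any(!is.na(inferred[obs_loci]))) {
        key <- .profile_key(inferred)
        if (!key %in% names(profiles)) {
          profiles[[key]] <- inferred
          sources[[key]] <- "inferred"
        }
        resolved <- all(!is.na(inferred[obs_loci]))
      }
    }
    if (!resolved) {
      dec <- .decompositions(s, obs_loci, max(n_resid, 0L),
                             fixed = consistent)
      if (is.null(dec)) {
        ambiguities[[ind]] <- tibble(
          individual_id = ind, n_strains = k, n_decompositions = NA_integer_,
          decompositions = list("enumeration refused: search space too large"))
      } else if (length(dec) == 0 && length(consistent) > 0) {
        ## anchors may not all be truly present; retry unconstrained
        dec <- .decompositions(s, obs_loci, k, fixed = list())
      }
      if (!is.null(dec) && !ind %in% names(ambiguities)) {
        if (length(dec) == 0) {
          conflicts[[ind]] <- tibble(
            individual_id = ind,
            reason = "no strain-set decomposition matches the observed alleles")
        } else {
          full <- lapply(dec, function(ch) c(consistent, ch))
          labels <- sort(unique(vapply(full, .decomp_label, character(1))))
          if (length(labels) == 1L) {
            ## a unique decomposition is a resolution, not an ambiguity
            for (p in dec[[1]]) {
              pf <- setNames(rep(NA_integer_, length(loci)), loci)
              pf[names(p)] <- p
              key <- .profile_key(pf)
              if (!key %in% names(profiles)) {
                profiles[[key]] <- pf
                sources[[key]] <- "inferred"
              }
            }
          } else {
            ambiguities[[ind]] <- tibble(
              individual_id = ind, n_strains = k,
              n_decompositions = length(labels),
              decompositions = list(labels))
          }
        }
      }
    }
  }
  prof_tbl <- bind_rows(lapply(names(profiles), function(key) {
    p <- profiles[[key]]
    tibble(profile_id = key, source = sources[[key]],
           complete = all(!is.na(p)),
           locus = names(p), allele_id = unname(p))
  }))
  structure(
    list(profiles = prof_tbl,
         ambiguities = if (length(ambiguities)) bind_rows(ambiguities)
                       else tibble(individual_id = character(0),
                                   n_strains = integer(0),
                                   n_decompositions = integer(0),
                                   decompositions = list()),
         conflicts = if (length(conflicts)) bind_rows(conflicts)
                     else tibble(individual_id = character(0),
                                 reason = character(0))),
    class = "mlst_intersection")
}

#' @exportS3Method generics::tidy
tidy.mlst_intersection <- function(x, ...) x$profiles

#' @exportS3Method generics::glance
glance.mlst_intersection <- function(x, ...) {
  tibble(n_profiles = length(unique(x$profiles$profile_id)),
         n_complete = sum(tapply(x$profiles$complete,
                                 x$profiles$profile_id, all)),
         n_ambiguous = nrow(x$ambiguities),
         n_conflicts = nrow(x$conflicts))
}

#' @export
print.mlst_intersection <- function(x, ...) {
  cat("Allelic intersection analysis\n")
  cat(sprintf("  profiles: %d (%d complete), ambiguous individuals: %d, conflicts: %d\n",
              length(unique(x$profiles$profile_id)),
              sum(tapply(x$profiles$complete, x$profiles$profile_id, all)),
              nrow(x$ambiguities), nrow(x$conflicts)))
  invisible(x)
}

#' Resolve co-infections by titer rank consistency
#'
#' Within each individual and locus, alleles are ranked by titer (highest
#' first). Alleles of the same rank across loci form a candidate strain: if
#' one strain is consistently at higher density than the other, its alleles
#' occupy rank 1 everywhere. A cell — one (individual, locus) ranking — is
#' a tie, hence unresolvable and excluded from the score denominator, when
#' adjacent titers are within `tie_ratio` of each other. The consistency
#' score is the fraction of resolvable cells whose allele-to-rank map
#' agrees with the locus's majority map across individuals.
#'
#' @param titers Tibble with columns `individual_id`, `locus`, `allele_id`,
#'   `titer` (positive relative copy numbers). Every locus must carry the
#'   same number of alleles (the presumed strain count) within each
#'   individual.
#' @param tie_ratio Titers whose ratio is below this are tied (default 1.5).
#' @param score_threshold Minimum consistency score for an assignment to be
#'   returned; below it only the ambiguity report is filled.
#' @return Object of class `mlst_titer`: list with `strains` (tibble
#'   `strain_rank`, `locus`, `allele_id`, `NULL` when below threshold),
#'   `score`, `resolved`, `n_cells`, `n_unresolvable`, and `ambiguous`
#'   (per-cell disagreement report).
#' @export
resolve_by_titer <- function(titers, tie_ratio = 1.5,
                             score_threshold = 0.8) {
  stopifnot(all(c("individual_id", "locus", "allele_id", "titer") %in%
                  names(titers)))
  if (any(titers$titer <= 0)) abort("titers must be positive")
  counts <- titers %>%
    group_by(.data$individual_id, .data$locus) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  per_ind <- split(counts, counts$individual_id)
  for (ind in names(per_ind)) {
    if (length(unique(per_ind[[ind]]$n)) > 1L) {
      msg <- paste(sprintf("%s=%d", per_ind[[ind]]$locus, per_ind[[ind]]$n),
                   collapse = ", ")
      abort(sprintf(
        "unequal allele counts across loci for individual %s: %s", ind, msg))
    }
  }
  ranked <- titers %>%
    group_by(.data$individual_id, .data$locus) %>%
    arrange(dplyr::desc(.data$titer), .data$allele_id, .by_group = TRUE) %>%
    mutate(
      rank = row_number(),
      tied = dplyr::n() > 1L &
        any(.data$titer[-dplyr::n()] / .data$titer[-1] < tie_ratio)
    ) %>%
    ungroup()
  resolvable <- filter(ranked, !.data$tied)
  if (nrow(resolvable) == 0) {
    return(structure(list(strains = NULL, score = NA_real_,
                          resolved = FALSE, n_cells = 0L,
                          n_unresolvable = nrow(distinct(
                            ranked, .data$individual_id, .data$locus)),
                          ambiguous = ranked),
                     class = "mlst_titer"))
  }
  ## majority rank per (locus, allele) over resolvable cells
  majority <- resolvable %>%
    group_by(.data$locus, .data$allele_id) %>%
    summarise(maj_rank = as.integer(names(which.max(table(.data$rank)))),
              .groups = "drop")
  scored <- resolvable %>%
    left_join(majority, by = c("locus", "allele_id")) %>%
    group_by(.data$individual_id, .data$locus) %>%
    summarise(agree = all(.data$rank == .data$maj_rank), .groups = "drop")
  score <- mean(scored$agree)
  n_cells_total <- nrow(distinct(ranked, .data$individual_id, .data$locus))
  strains <- majority %>%
    rename(strain_rank = "maj_rank") %>%
    select("strain_rank", "locus", "allele_id") %>%
    arrange(.data$strain_rank, .data$locus)
  resolved <- score >= score_threshold
  structure(
    list(strains = if (resolved) strains else NULL,
         score = score, resolved = resolved,
         n_cells = nrow(scored),
         n_unresolvable = n_cells_total - nrow(scored),
         ambiguous = if (resolved) filter(scored, !.data$agree)
                     else strains),
    class = "mlst_titer")
}

#' @exportS3Method generics::tidy
tidy.mlst_titer <- function(x, ...) {
  if (is.null(x$strains)) x$ambiguous else x$strains
}

#' @exportS3Method generics::glance
glance.mlst_titer <- function(x, ...) {
  tibble(score = x$score, resolved = x$resolved,
         n_cells = x$n_cells, n_unresolvable = x$n_unresolvable)
}

#' @export
print.mlst_titer <- function(x, ...) {
  cat(sprintf(
    "Titer rank-consistency analysis: score %.3f over %d cells (%d tied), %s\n",
    x$score, x$n_cells, x$n_unresolvable,
    if (x$resolved) "assignment returned" else "below threshold"))
  invisible(x)
}

#' Titer plot for co-infection resolution
#'
#' Log-scale titers per locus, coloured by allele, one line per individual
#' chain — a visual check that one allele set sits consistently above the
#' other.
#'
#' @param titers Tibble as for [resolve_by_titer()].
#' @return A ggplot object.
#' @export
plot_titers <- function(titers) {
  ggplot2::ggplot(titers,
                  ggplot2::aes(x = .data$locus, y = .data$titer,
                               colour = factor(.data$allele_id),
                               group = interaction(.data$individual_id,
                                                   .data$allele_id))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(colour = "allele", y = "relative titer (log scale)") +
    ggplot2::theme_minimal()
}
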