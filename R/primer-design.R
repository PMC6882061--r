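## Degenerate primer design from multi-strain alignments. Candidate windows
## are IUPAC consensus slices of the alignment, ranked by (degeneracy,
## 3'-conserved run, hairpin/dimer heuristics). The structure checks are
## deliberately simple, deterministic complementarity-run heuristics, not a
## nearest-neighbor thermodynamic model.

.set_to_code <- local({
  codes <- iupac_codes("universal")
  keys <- vapply(codes[setdiff(names(codes), c("I", "-"))],
                 function(b) paste(sort(b), collapse = ""), character(1))
  setNames(names(keys), keys)
})

#' Minimal IUPAC code for an alignment column
#'
#' Returns the unique IUPAC symbol whose allowed set equals the set of
#' distinct bases observed in the column. Gaps are ignored; an all-gap
#' column yields the sentinel `NA`.
#'
#' @param bases Character vector of observed bases (A/C/G/T or `-`).
#' @return Single IUPAC character, or `NA_character_` for an uncallable
#'   (all-gap) column.
#' @examples
#' column_consensus(c("C", "T", "C")) # "Y"
#' @export
column_consensus <- function(bases) {
  bases <- toupper(bases)
  bases <- bases[bases != "-"]
  if (length(bases) == 0) return(NA_character_)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort("column_consensus expects concrete A/C/G/T (and gap) observations")
  }
  unname(.set_to_code[[paste(sort(unique(bases)), collapse = "")]])
}

#' IUPAC consensus of an alignment
#'
#' @param alignment Tibble (`id`, `seq`) or named character vector of
#'   equal-length sequences.
#' @return Single consensus string; all-gap columns become `N` with a
#'   warning (they are uncallable for primer purposes).
#' @export
consensus_sequence <- function(alignment) {
  aln <- .as_alignment(alignment)
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  cons <- apply(mat, 2, column_consensus)
  if (anyNA(cons)) {
    warn("all-gap column(s) in alignment; consensus set to N there")
    cons[is.na(cons)] <- "N"
  }
  paste(cons, collapse = "")
}

## length of the degeneracy-free suffix (3' conserved run) of a primer
.three_prime_run <- function(seq) {
  chars <- rev(.seq_chars(seq))
  run <- 0L
  for (ch in chars) {
    if (ch %in% c("A", "C", "G", "T")) run <- run + 1L else break
  }
  run
}

## TRUE where code x can pair with code y under some allowed-base choice
.can_pair <- function(x, y, mask = .code_mask()) {
  comp <- unname(.iupac_complement[x])
  bitwAnd(mask[comp], mask[y]) > 0L
}

#' Hairpin self-complementarity score
#'
#' Longest self-foldback stem: the maximal run length L for which two
#' disjoint stretches of the primer, separated by a loop of at least
#' `min_loop` bases, are complementary in antiparallel orientation.
#' Degenerate positions count as pairable if any allowed base pairing
#' complements.
#'
#' @param seq Ungapped primer sequence.
#' @param min_loop Minimum loop length between the stem halves.
#' @return Non-negative integer stem length.
#' @export
hairpin_score <- function(seq, min_loop = 3) {
  s <- normalize_seq(seq, allow_gap = FALSE)
  chars <- .seq_chars(s)
  n <- length(chars)
  mask <- .code_mask()
  best <- 0L
  ## pair (i..i+L-1) with (j..j+L-1) read backwards; loop = j - (i+L-1) - 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      L <- 0L
      while (i + L <= n && j - L >= 1 && j - L > i + L &&
             .can_pair(chars[i + L], chars[j - L], mask)) {
        if ((j - L) - (i + L) - 1 >= min_loop) best <- max(best, L + 1L)
        L <- L + 1L
      }
    }
  }
  best
}

#' Primer-dimer complementarity score
#'
#' Longest contiguous antiparallel complementary run between two primers
#' over all relative offsets (equivalently, the longest run of positions
#' where `a` matches `revcomp(b)` at some alignment offset). 3'-anchored
#' runs — runs that involve the 3'-terminal base of either primer — are
#' scored separately since they prime extension.
#'
#' @param a,b Ungapped primer sequences (use `b = a` for self-dimers).
#' @return Tibble with columns `score` and `three_prime_score`.
#' @export
dimer_score <- function(a, b) {
  sa <- normalize_seq(a, allow_gap = FALSE)
  sb <- normalize_seq(b, allow_gap = FALSE)
  ca <- .seq_chars(sa)
  cb <- .seq_chars(sb)
  na_ <- length(ca); nb <- length(cb)
  mask <- .code_mask()
  best <- 0L; best3 <- 0L
  ## antiparallel duplex: a position i pairs with b position j with
  ## i + j constant per offset; consecutive stacked pairs are (i+1, j-1)
  for (k in seq_len(na_ + nb - 1)) {
    i0 <- max(1L, k + 1L - nb)
    i1 <- min(na_, k)
    run <- 0L
    run_starts_at_b3 <- FALSE
    for (i in i0:i1) {
      j <- k + 1L - i
      if (.can_pair(ca[i], cb[j], mask)) {
        if (run == 0L) run_starts_at_b3 <- (j == nb)
        run <- run + 1L
      } else {
        run <- 0L
      }
      if (run > best) best <- run
      ## 3'-anchored: run covers the 3'-terminal base of a (i == na_) or of
      ## b (run began at j == nb, since j decreases along the run)
      if (run > 0L && (i == na_ || run_starts_at_b3) && run > best3) {
        best3 <- run
      }
    }
  }
  tibble(score = best, three_prime_score = best3)
}

#' Melting temperature estimate
#'
#' Wallace rule `2(A+T) + 4(G+C)` for sequences of 14 bases or fewer, and
#' the GC/length formula `64.9 + 41 * (GC - 16.4) / length` above that.
#' Degenerate positions contribute their expected A+T and G+C content
#' (the mean over the full expansion), so the estimate is deterministic.
#'
#' @param seq Ungapped primer sequence.
#' @return Estimated melting temperature in degrees Celsius.
#' @examples
#' tm_estimate("AAAATTTT") # 16
#' @export
tm_estimate <- function(seq) {
  s <- normalize_seq(seq, allow_gap = FALSE)
  codes <- iupac_codes("universal")
  gc_frac <- vapply(.seq_chars(s), function(ch) {
    allowed <- codes[[ch]]
    if (length(allowed) == 0) return(0.5) # strict inosine: neutral
    mean(allowed %in% c("G", "C"))
  }, numeric(1))
  n <- length(gc_frac)
  gc <- sum(gc_frac)
  at <- n - gc
  if (n <= 14) 2 * at + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
}

.default_m13 <- c(forward = "TGTAAAACGACGGCCAGT",  # -21 M13F
                  reverse = "CAGGAAACAGCTATGAC")   # M13R

#' Add or strip an M13 sequencing tag
#'
#' Forward primers receive the M13F tag, reverse primers M13R, prepended at
#' the 5' end. Tags serve Sanger sequencing only and are excluded from all
#' binding-site and trimming arithmetic, so tagging must be undone (or the
#' untagged sequence kept) before in-silico PCR.
#'
#' @param seq Primer sequence (untagged for `tag_m13`, tagged for
#'   `strip_m13`).
#' @param orientation `"forward"` or `"reverse"`.
#' @param tags Named character vector with elements `forward`, `reverse`.
#' @return Tagged (resp. stripped) sequence string.
#' @export
tag_m13 <- function(seq, orientation = c("forward", "reverse"),
                    tags = .default_m13) {
  orientation <- match.arg(orientation)
  s <- normalize_seq(seq, allow_gap = FALSE)
  tag <- tags[[orientation]]
  if (startsWith(s, tag)) abort("primer already carries its M13 tag")
  paste0(tag, s)
}

#' @rdname tag_m13
#' @export
strip_m13 <- function(seq, orientation = c("forward", "reverse"),
                      tags = .default_m13) {
  orientation <- match.arg(orientation)
  s <- normalize_seq(seq, allow_gap = FALSE)
  tag <- tags[[orientation]]
  if (!startsWith(s, tag)) abort("sequence does not start with the M13 tag")
  substr(s, nchar(tag) + 1L, nchar(s))
}

#' Design degenerate primers from a multi-strain alignment
#'
#' Scans every window of the consensus in the requested length range, in
#' both orientations (reverse candidates are the reverse complement of the
#' consensus window), keeps windows whose degeneracy and 3'-conserved run
#' pass the thresholds, and ranks candidates by fewest ambiguities first,
#' then longest 3' conserved run, then smallest hairpin + dimer score, then
#' leftmost window (a deterministic tie-break). Output is invariant to the
#' order of sequences in the alignment.
#'
#' @param alignment Tibble (`id`, `seq`) or named character vector; at least
#'   two equal-length sequences.
#' @param length_range Two-element integer vector, min and max primer length.
#' @param max_degeneracy Keep windows with degeneracy at or below this.
#' @param min_three_prime_run Required degeneracy-free 3' suffix (bases).
#' @return Tibble of candidates: `seq`, `orientation`, `start`, `end`
#'   (1-based inclusive on the alignment), `degeneracy`, `three_prime_run`,
#'   `hairpin`, `self_dimer`, `tm`, `rank`. Empty (zero rows) with a
#'   `best_failing` attribute describing the closest-missing window when
#'   nothing passes.
#' @export
design_primers <- function(alignment, length_range = c(18L, 25L),
                           max_degeneracy = 96, min_three_prime_run = 3L) {
  aln <- .as_alignment(alignment)
  if (length(aln) < 2) abort("primer design needs at least two sequences")
  cons <- consensus_sequence(aln)
  ncol_ <- nchar(cons)
  lens <- seq.int(length_range[1], min(length_range[2], ncol_))
  rows <- list()
  fails <- list()
  for (L in lens) {
    for (s in seq_len(ncol_ - L + 1L)) {
      win <- substr(cons, s, s + L - 1L)
      if (grepl("-", win, fixed = TRUE)) next
      d <- degeneracy(win)
      for (orient in c("forward", "reverse")) {
        cand <- if (orient == "forward") win else revcomp(win)
        run3 <- .three_prime_run(cand)
        if (d <= max_degeneracy && run3 >= min_three_prime_run) {
          rows[[length(rows) + 1L]] <- tibble(
            seq = cand, orientation = orient,
            start = s, end = s + L - 1L,
            degeneracy = d, three_prime_run = run3
          )
        } else {
          fails[[length(fails) + 1L]] <- tibble(
            seq = cand, orientation = orient, start = s, end = s + L - 1L,
            degeneracy = d, three_prime_run = run3
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    out <- tibble(seq = character(), orientation = character(),
                  start = integer(), end = integer(),
                  degeneracy = numeric(), three_prime_run = integer(),
                  hairpin = integer(), self_dimer = integer(),
                  tm = numeric(), rank = integer())
    if (length(fails) > 0) {
      fl <- bind_rows(fails) %>%
        arrange(.data$degeneracy, dplyr::desc(.data$three_prime_run),
                .data$start)
      attr(out, "best_failing") <- fl[1, ]
    }
    return(out)
  }
  out <- bind_rows(rows) %>%
    mutate(
      hairpin = vapply(.data$seq, hairpin_score, integer(1)),
      self_dimer = vapply(.data$seq,
                          function(x) dimer_score(x, x)$score, integer(1)),
      tm = vapply(.data$seq, tm_estimate, numeric(1))
    ) %>%
    arrange(.data$degeneracy, dplyr::desc(.data$three_prime_run),
            .data$hairpin + .data$self_dimer, .data$start,
            .data$orientation) %>%
    mutate(rank = row_number())
  out
}
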