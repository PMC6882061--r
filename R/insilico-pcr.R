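## In-silico PCR: locate degenerate-primer binding sites on a concrete
## template, pair opposite-strand hits into amplicons, and trim primer
## footprints to the MLST fragment. Coordinates are 1-based inclusive on
## the + strand throughout.

## mismatch counts of `primer` against every window of `tmpl` (both as
## character vectors); returns integer vector over start offsets
.scan_mismatches <- function(primer_chars, tmpl_chars, mask,
                             tail_len = 0L) {
  m <- length(primer_chars)
  n <- length(tmpl_chars)
  if (n < m) return(list(total = integer(0), tail = integer(0)))
  tmpl_bits <- .base_bits[tmpl_chars]
  n_off <- n - m + 1L
  total <- integer(n_off)
  tail_mm <- integer(n_off)
  for (p in seq_len(m)) {
    ok <- bitwAnd(mask[[primer_chars[p]]], tmpl_bits[p:(p + n_off - 1L)]) > 0L
    total <- total + !ok
    if (tail_len > 0L && p > m - tail_len) tail_mm <- tail_mm + !ok
  }
  list(total = total, tail = tail_mm)
}

#' Find primer binding sites on a template
#'
#' Scans both strands of a concrete template for windows matching a
#' degenerate primer with at most `max_mismatches` mismatches and no
#' mismatch in the primer's 3'-terminal `three_prime_exact` bases (3'
#' fidelity governs polymerase extension). Positions are 1-based on the
#' + strand; for a `-` strand site the primer anneals to the reverse
#' strand and its 3' end faces left.
#'
#' @param primer Degenerate primer sequence (untagged).
#' @param template Concrete A/C/G/T template string.
#' @param max_mismatches Mismatch tolerance outside the 3' window.
#' @param three_prime_exact Number of 3'-terminal primer bases required to
#'   match exactly.
#' @param template_id Label copied into the output.
#' @param inosine Inosine policy, see [iupac_codes()].
#' @return Tibble `template_id`, `start`, `end`, `strand`, `mismatches`.
#' @export
find_binding_sites <- function(primer, template, max_mismatches = 0L,
                               three_prime_exact = 3L,
                               template_id = "template",
                               inosine = "universal") {
  p <- normalize_seq(primer, allow_gap = FALSE)
  t_ <- normalize_seq(template, allow_gap = FALSE)
  tc <- .seq_chars(t_)
  if (!all(tc %in% c("A", "C", "G", "T"))) {
    abort("template must be concrete A/C/G/T")
  }
  mask <- .code_mask(inosine)
  m <- nchar(p)
  hit_tbl <- function(scan, strand, tail_from_left) {
    keep <- which(scan$total <= max_mismatches & scan$tail == 0L)
    if (length(keep) == 0) {
      return(tibble(template_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    mismatches = integer(0)))
    }
    tibble(template_id = template_id, start = keep,
           end = keep + m - 1L, strand = strand,
           mismatches = scan$total[keep])
  }
  ## + strand: primer as given, 3' end at the right of the window
  fwd <- .scan_mismatches(.seq_chars(p), tc, mask,
                          tail_len = three_prime_exact)
  ## - strand: revcomp(primer) on the + strand; the primer's 3'-terminal
  ## bases are the *first* bases of the reverse-complemented pattern, so
  ## scan the reversed pattern against the reversed template to reuse the
  ## tail logic, then map offsets back
  rc <- revcomp(p)
  rev_scan <- .scan_mismatches(rev(.seq_chars(rc)), rev(tc), mask,
                               tail_len = three_prime_exact)
  n <- length(tc)
  if (length(rev_scan$total) > 0) {
    map_back <- function(v) rev(v)
    rev_scan <- list(total = map_back(rev_scan$total),
                     tail = map_back(rev_scan$tail))
  }
  bind_rows(hit_tbl(fwd, "+"), hit_tbl(rev_scan, "-")) %>%
    arrange(.data$start, .data$strand)
}

#' Predict PCR products for a primer pair
#'
#' Every combination of a forward-primer site on the + strand and a
#' reverse-primer site on the - strand, with the forward footprint entirely
#' left of the reverse footprint and a product size inside `size_window`,
#' yields one amplicon. An empty result means no product (some templates
#' simply fail to amplify); it is not an error.
#'
#' @param pair One row of [scheme_pairs()] (or any list with `locus`,
#'   `fwd_seq`, `rev_seq` and optionally `fragment_size`, `alt_seq`).
#' @param template Concrete template string.
#' @param size_window Two-element numeric product-size interval. The default
#'   is the registered fragment size plus both primer lengths, plus or minus
#'   20 percent; unlimited if no fragment size is registered.
#' @param use_alt_forward Amplify with the alternative forward primer (where
#'   the scheme carries one) instead of the primary forward.
#' @inheritParams find_binding_sites
#' @return Tibble of amplicons: `template_id`, `locus`, `start`, `end`,
#'   `length`, `fwd_mismatches`, `rev_mismatches`, `fwd_len`, `rev_len`,
#'   `seq`.
#' @export
amplify <- function(pair, template, max_mismatches = 0L,
                    three_prime_exact = 3L, size_window = NULL,
                    template_id = "template", use_alt_forward = FALSE,
                    inosine = "universal") {
  fwd_seq <- if (use_alt_forward) pair$alt_seq else pair$fwd_seq
  if (is.null(fwd_seq) || is.na(fwd_seq)) abort("no forward primer available")
  rev_seq <- pair$rev_seq
  locus <- if (!is.null(pair$locus)) pair$locus else NA_character_
  if (is.null(size_window)) {
    fs <- if (!is.null(pair$fragment_size)) pair$fragment_size else NA
    size_window <- if (is.na(fs) || isTRUE(use_alt_forward)) {
      c(1, Inf)
    } else {
      expected <- fs + nchar(fwd_seq) + nchar(rev_seq)
      c(floor(0.8 * expected), ceiling(1.2 * expected))
    }
  }
  f_sites <- find_binding_sites(fwd_seq, template, max_mismatches,
                                three_prime_exact, template_id, inosine) %>%
    filter(.data$strand == "+")
  r_sites <- find_binding_sites(rev_seq, template, max_mismatches,
                                three_prime_exact, template_id, inosine) %>%
    filter(.data$strand == "-")
  empty <- tibble(template_id = character(0), locus = character(0),
                  start = integer(0), end = integer(0), length = integer(0),
                  fwd_mismatches = integer(0), rev_mismatches = integer(0),
                  fwd_len = integer(0), rev_len = integer(0),
                  seq = character(0))
  if (nrow(f_sites) == 0 || nrow(r_sites) == 0) return(empty)
  combos <- tidyr::expand_grid(fi = seq_len(nrow(f_sites)),
                               ri = seq_len(nrow(r_sites)))
  rows <- purrr::pmap(combos, function(fi, ri) {
    f <- f_sites[fi, ]; r <- r_sites[ri, ]
    len <- r$end - f$start + 1L
    if (f$end >= r$start || len < size_window[1] || len > size_window[2]) {
      return(NULL)
    }
    tibble(template_id = template_id, locus = locus,
           start = f$start, end = r$end, length = len,
           fwd_mismatches = f$mismatches, rev_mismatches = r$mismatches,
           fwd_len = nchar(fwd_seq), rev_len = nchar(rev_seq),
           seq = substr(template, f$start, r$end))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) empty else arrange(out, .data$start, .data$end)
}

#' Trim primer footprints from amplicons
#'
#' Removes the forward footprint from the left end and the reverse footprint
#' from the right end of each amplicon, leaving the MLST fragment that is
#' actually typed and aligned. An amplicon exactly equal to the two primer
#' footprints yields the empty-fragment sentinel (`""`).
#'
#' @param amplicons Tibble from [amplify()].
#' @return The input with `fragment` and `fragment_length` columns added.
#' @export
trim_primers <- function(amplicons) {
  if (nrow(amplicons) == 0) {
    return(mutate(amplicons, fragment = character(0),
                  fragment_length = integer(0)))
  }
  short <- amplicons$length < amplicons$fwd_len + amplicons$rev_len
  if (any(short)) {
    abort(sprintf(
      "amplicon of length %d is shorter than its combined primers (%d bp)",
      amplicons$length[which(short)[1]],
      (amplicons$fwd_len + amplicons$rev_len)[which(short)[1]]))
  }
  amplicons %>%
    mutate(
      fragment = substr(.data$seq, .data$fwd_len + 1L,
                        .data$length - .data$rev_len),
      fragment_length = .data$length - .data$fwd_len - .data$rev_len
    )
}
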