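## IUPAC nucleotide machinery. Every other module sits on these primitives,
## so the contracts here are strict: sequences are uppercase A/C/G/T plus
## the 15 standard ambiguity codes, inosine (I) and the alignment gap "-".

#' IUPAC code table
#'
#' Returns the allowed-base sets for the nucleotide alphabet used throughout
#' the package: the four bases, the eleven standard ambiguity codes, inosine
#' (`I`) and the gap (`-`). Inosine is a universal-pairing nucleoside used at
#' hypervariable primer positions; by default it matches all four bases.
#'
#' @param inosine `"universal"` (I matches A/C/G/T; the reason inosine is put
#'   in primers) or `"strict"` (I never matches a template base and
#'   contributes 1 to degeneracy).
#' @return Named list mapping each symbol to its character vector of allowed
#'   bases (`character(0)` for the gap, and for `I` under `"strict"`).
#' @export
iupac_codes <- function(inosine = c("universal", "strict")) {
  inosine <- match.arg(inosine)
  codes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"),
    I = if (inosine == "universal") c("A", "C", "G", "T") else character(0),
    `-` = character(0)
  )
  codes
}

## complement pairs; S, W, N are self-complementary, I complements itself
## (universal pairing), gap maps to gap.
.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", I = "I", `-` = "-"
)

.iupac_alphabet <- names(.iupac_complement)

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts U to T, and validates against the IUPAC alphabet.
#' The error for an invalid character names the character and its position
#' (and the sequence label when given).
#'
#' @param seq Single character string.
#' @param id Optional label used in error messages.
#' @param allow_gap Permit `-`? Primers never carry gaps; alignments may.
#' @return Normalized string.
#' @export
normalize_seq <- function(seq, id = NULL, allow_gap = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  ok <- chars %in% .iupac_alphabet
  if (!allow_gap) ok <- ok & chars != "-"
  if (!all(ok)) {
    bad <- which(!ok)[1]
    where <- if (is.null(id)) "" else paste0(" in '", id, "'")
    abort(sprintf("invalid nucleotide character '%s' at position %d%s",
                  chars[bad], bad, where))
  }
  s
}

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Reverse complement with IUPAC codes
#'
#' @param seq Character string over the IUPAC alphabet (gaps allowed and
#'   preserved). `revcomp()` is an involution.
#' @return Reverse-complemented string.
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("ATGCAY") # "RTGCAT"
#' @export
revcomp <- function(seq) {
  s <- normalize_seq(seq)
  chars <- .seq_chars(s)
  paste(rev(unname(.iupac_complement[chars])), collapse = "")
}

#' Degeneracy of a degenerate sequence
#'
#' Product over positions of the number of bases each code allows. A fully
#' concrete primer has degeneracy 1; `N` contributes 4. Gap characters are
#' rejected: degeneracy is a primer-space notion.
#'
#' @inheritParams revcomp
#' @param inosine Inosine policy, see [iupac_codes()].
#' @return Positive number (may exceed integer range for long, highly
#'   degenerate strings).
#' @examples
#' degeneracy("ACGT") # 1
#' degeneracy("ATGCAYGTMACBGGDTTTARAAG") # 72
#' @export
degeneracy <- function(seq, inosine = "universal") {
  s <- normalize_seq(seq, allow_gap = FALSE)
  codes <- iupac_codes(inosine)
  sizes <- vapply(.seq_chars(s), function(ch) {
    k <- length(codes[[ch]])
    if (ch == "I" && k == 0L) 1L else k
  }, integer(1))
  prod(sizes)
}

#' Expand a degenerate sequence into its concrete realizations
#'
#' @inheritParams degeneracy
#' @param cap Refuse to expand if the degeneracy exceeds this bound; the
#'   error reports the computed degeneracy.
#' @return Character vector of all A/C/G/T sequences the pattern matches,
#'   of length `degeneracy(seq)`.
#' @examples
#' expand_degenerate("AY") # "AC" "AT"
#' @export
expand_degenerate <- function(seq, cap = 4096, inosine = "universal") {
  s <- normalize_seq(seq, allow_gap = FALSE)
  d <- degeneracy(s, inosine)
  if (d > cap) {
    abort(sprintf("degeneracy %d of '%s' exceeds the expansion cap %d",
                  d, s, cap))
  }
  codes <- iupac_codes(inosine)
  sets <- lapply(.seq_chars(s), function(ch) {
    allowed <- codes[[ch]]
    if (length(allowed) == 0L) ch else allowed
  })
  out <- ""
  for (set in sets) out <- as.vector(outer(out, set, paste0))
  sort(out)
}

#' Mismatches between a degenerate primer and a concrete window
#'
#' Counts the positions where the window base is outside the primer code's
#' allowed set. Both arguments must have equal length; the window must be
#' concrete A/C/G/T.
#'
#' @param primer,window Equal-length strings; `window` concrete.
#' @inheritParams degeneracy
#' @return Non-negative integer.
#' @export
match_mismatches <- function(primer, window, inosine = "universal") {
  p <- normalize_seq(primer, allow_gap = FALSE)
  w <- normalize_seq(window, allow_gap = FALSE)
  pc <- .seq_chars(p); wc <- .seq_chars(w)
  if (length(pc) != length(wc)) {
    abort(sprintf("length mismatch: primer has %d bases, window %d",
                  length(pc), length(wc)))
  }
  if (!all(wc %in% c("A", "C", "G", "T"))) {
    abort("window must be a concrete A/C/G/T sequence")
  }
  codes <- iupac_codes(inosine)
  sum(vapply(seq_along(pc),
             function(i) !(wc[i] %in% codes[[pc[i]]]),
             logical(1)))
}

## Integer encoding used by the scanning code: bitmask over A=1 C=2 G=4 T=8.
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.code_mask <- function(inosine = "universal") {
  codes <- iupac_codes(inosine)
  vapply(codes, function(allowed) {
    if (length(allowed) == 0L) 0L else sum(.base_bits[allowed])
  }, integer(1))
}
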