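## Pairwise distances feeding the NJ builder. p-distance (mismatch
## fraction) and the JC69 correction d = -(3/4) ln(1 - (4/3) p), with
## pairwise deletion of gapped/ambiguous sites.

#' Pairwise distance matrix from an alignment
#'
#' Sites where either sequence carries a gap or ambiguity code are dropped
#' per pair (pairwise deletion). Under `model = "JC69"` a mismatch fraction
#' at or beyond the 0.75 saturation point has no finite correction; such
#' entries are flagged in the `"saturated"` attribute and replaced by twice
#' the largest finite distance in the matrix (5.0 if there is none), with a
#' warning — the matrix contract forbids NaN.
#'
#' @param alignment Tibble (`id`, `seq`) or named character vector of
#'   equal-length sequences (at least two).
#' @param model `"p"` (mismatch fraction) or `"JC69"`.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames,
#'   and a logical `"saturated"` attribute matrix under JC69.
#' @export
pairwise_distance <- function(alignment, model = c("p", "JC69")) {
  model <- match.arg(model)
  aln <- .as_alignment(alignment)
  n <- length(aln)
  if (n < 2) abort("at least two sequences are required")
  mat <- do.call(rbind, strsplit(toupper(unname(aln)), "", fixed = TRUE))
  concrete <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  taxa <- names(aln)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- concrete[i, ] & concrete[j, ]
      n_use <- sum(use)
      if (n_use == 0) {
        abort(sprintf("no comparable sites between '%s' and '%s'",
                      taxa[i], taxa[j]))
      }
      p <- sum(mat[i, use] != mat[j, use]) / n_use
      if (model == "p") {
        d[i, j] <- d[j, i] <- p
      } else if (p >= 0.75) {
        sat[i, j] <- sat[j, i] <- TRUE
        d[i, j] <- d[j, i] <- NA_real_ # placeholder, patched below
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (any(sat)) {
    finite_max <- suppressWarnings(max(d[!is.na(d)]))
    fill <- if (is.finite(finite_max) && finite_max > 0) 2 * finite_max else 5
    d[is.na(d)] <- fill
    warn(sprintf(
      "%d saturated pair(s) (p >= 0.75) replaced by %.3g; see attr 'saturated'",
      sum(sat) / 2, fill))
  }
  if (model == "JC69") attr(d, "saturated") <- sat
  d
}
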