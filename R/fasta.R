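## FASTA I/O. Biostrings does the parsing/wrapping; validation of the
## residues (with file + record + position in the message) is ours, because
## the package's alphabet includes inosine which DNAStringSet rejects.

#' Read a FASTA file into a tibble
#'
#' Multi-record, wrapped or single-line FASTA. Sequences are normalized
#' (uppercase, U to T) and validated; an invalid residue is reported with
#' file, record id and position.
#'
#' @param path FASTA file.
#' @param allow_gap Permit alignment gaps (`-`).
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path, allow_gap = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  seqs <- vapply(seq_along(seqs), function(i) {
    tryCatch(
      normalize_seq(seqs[[i]], id = ids[[i]], allow_gap = allow_gap),
      error = function(e) {
        abort(sprintf("%s (file '%s', record %d)",
                      conditionMessage(e), path, i))
      }
    )
  }, character(1))
  tibble(id = ids, seq = unname(seqs))
}

#' Write a tibble of sequences as FASTA
#'
#' @param x Tibble with columns `id` and `seq` (or a named character vector).
#' @param path Output file.
#' @param width Line-wrap width; `Inf` writes single-line records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(id = names(x), seq = unname(x))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  ss <- Biostrings::BStringSet(setNames(x$seq, x$id))
  if (is.finite(width)) {
    Biostrings::writeXStringSet(ss, path, width = width)
  } else {
    Biostrings::writeXStringSet(ss, path, width = max(nchar(x$seq), 1L))
  }
  invisible(path)
}

## alignment helper: named character vector from a tibble or vector, with
## equal-length check
.as_alignment <- function(x, what = "alignment") {
  if (is.data.frame(x)) x <- setNames(x$seq, x$id)
  stopifnot(is.character(x))
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    abort(sprintf("%s must have unique sequence names", what))
  }
  if (length(unique(nchar(x))) > 1L) {
    abort(sprintf("%s sequences must be equal length", what))
  }
  x
}
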