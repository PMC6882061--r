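## The four-locus Cardinium primer scheme (gyrB, groEL, sufB, EF-G) ships
## as a TSV so user-defined schemes use the same loader. Coordinates are
## 1-based inclusive on the gene.

#' Load a primer scheme
#'
#' A scheme TSV has columns `primer_name`, `sequence`, `role`
#' (forward/reverse/alt_forward), `locus`, `tm_c`, `gene_length`,
#' `amp_start`, `amp_end`, `fragment_size`. Sequences are validated on load;
#' primer names must be unique.
#'
#' @param path Scheme TSV; defaults to the built-in Cardinium MLST scheme.
#' @return Tibble of primers with one row per primer.
#' @export
load_scheme <- function(path = cardinium_scheme_path()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("primer_name", "sequence", "role", "locus", "tm_c",
            "gene_length", "amp_start", "amp_end", "fragment_size")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("scheme file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$primer_name)) abort("primer names must be unique")
  x$sequence <- vapply(seq_len(nrow(x)), function(i) {
    normalize_seq(x$sequence[i], id = x$primer_name[i], allow_gap = FALSE)
  }, character(1))
  bad_role <- setdiff(x$role, c("forward", "reverse", "alt_forward"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown primer role: ", paste(bad_role, collapse = ", ")))
  }
  as_tibble(x)
}

#' Path of the shipped Cardinium scheme file
#' @return File path inside the installed package.
#' @export
cardinium_scheme_path <- function() {
  system.file("extdata", "cardinium_mlst_scheme.tsv",
              package = "cardmlst", mustWork = TRUE)
}

#' Primer pairs of a scheme
#'
#' Collapses a primer table to one row per locus: forward and reverse primer
#' (plus any alternative forward, carried but excluded from fragment-length
#' arithmetic), amplified range, and the registered fragment size.
#'
#' @param scheme Tibble from [load_scheme()].
#' @return Tibble with one row per locus, columns `locus`, `forward`,
#'   `fwd_seq`, `reverse`, `rev_seq`, `alt_forward`, `alt_seq`, `tm_c`,
#'   `gene_length`, `amp_start`, `amp_end`, `fragment_size`.
#' @export
scheme_pairs <- function(scheme = load_scheme()) {
  scheme %>%
    group_by(.data$locus) %>%
    summarise(
      forward = .data$primer_name[.data$role == "forward"][1],
      fwd_seq = .data$sequence[.data$role == "forward"][1],
      reverse = .data$primer_name[.data$role == "reverse"][1],
      rev_seq = .data$sequence[.data$role == "reverse"][1],
      alt_forward = .data$primer_name[.data$role == "alt_forward"][1],
      alt_seq = .data$sequence[.data$role == "alt_forward"][1],
      tm_c = .data$tm_c[1],
      gene_length = .data$gene_length[1],
      amp_start = .data$amp_start[1],
      amp_end = .data$amp_end[1],
      fragment_size = .data$fragment_size[1],
      .groups = "drop"
    )
}

#' Validate scheme arithmetic
#'
#' For each locus, checks that the amplified range lies within the gene and
#' recomputes the trimmed fragment length as
#' `span - len(forward) - len(reverse)` with `span = amp_end - amp_start + 1`.
#' Registered fragment sizes that disagree with this arithmetic are
#' *reported*, never silently corrected: the shipped Cardinium scheme stores
#' its published sufB and groEL sizes verbatim, and those two rows are known
#' not to close under the span arithmetic.
#'
#' @param scheme Tibble from [load_scheme()].
#' @return A `mlst_scheme_validation` tibble: `locus`, `span`, `fwd_len`,
#'   `rev_len`, `computed_fragment`, `registered_fragment`, `consistent`.
#' @export
validate_scheme <- function(scheme = load_scheme()) {
  pairs <- scheme_pairs(scheme)
  ## every primer must survive degeneracy + revcomp (errors propagate)
  invisible(lapply(scheme$sequence, function(s) {
    degeneracy(s)
    revcomp(s)
  }))
  out <- pairs %>%
    mutate(
      span = .data$amp_end - .data$amp_start + 1L,
      fwd_len = nchar(.data$fwd_seq),
      rev_len = nchar(.data$rev_seq),
      computed_fragment = .data$span - .data$fwd_len - .data$rev_len,
      registered_fragment = .data$fragment_size,
      consistent = .data$computed_fragment == .data$registered_fragment,
      range_ok = .data$amp_start >= 1L & .data$amp_end <= .data$gene_length
    ) %>%
    select("locus", "span", "fwd_len", "rev_len", "computed_fragment",
           "registered_fragment", "consistent", "range_ok")
  if (any(!out$range_ok)) {
    abort(paste0("amplified range outside gene for locus: ",
                 paste(out$locus[!out$range_ok], collapse = ", ")))
  }
  structure(out, class = c("mlst_scheme_validation", class(out)))
}

#' @exportS3Method generics::tidy
tidy.mlst_scheme_validation <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.mlst_scheme_validation <- function(x, ...) {
  tibble(
    n_loci = nrow(x),
    n_consistent = sum(x$consistent),
    n_inconsistent = sum(!x$consistent),
    total_registered_bp = sum(x$registered_fragment)
  )
}

#' @export
print.mlst_scheme_validation <- function(x, ...) {
  NextMethod()
  bad <- x[!x$consistent, , drop = FALSE]
  if (nrow(bad) > 0) {
    cat(sprintf(
      "Note: %d locus/loci with registered fragment size differing from span arithmetic: %s\n",
      nrow(bad),
      paste(sprintf("%s (computed %d, registered %d)", bad$locus,
                    bad$computed_fragment, bad$registered_fragment),
            collapse = "; ")))
  }
  invisible(x)
}
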