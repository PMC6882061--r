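## MLST bookkeeping: append-only allele databases per locus, allelic
## profiles, and sequence-type registries. Allele identity is exact
## sequence equality (the MLST convention); near-matches surface as new
## alleles with a nearest-allele note rather than being clustered.

#' Create an empty allele database
#'
#' @return Zero-row tibble with columns `locus`, `allele_id`, `seq`.
#' @export
new_allele_db <- function() {
  tibble(locus = character(0), allele_id = integer(0), seq = character(0))
}

## Hamming distance between equal-length concrete strings
.hamming <- function(a, b) {
  sum(.seq_chars(a) != .seq_chars(b))
}

#' Call an allele against a database
#'
#' Exact-match lookup with append-on-miss: a fragment identical to a
#' registered allele returns that allele's id; otherwise it is appended
#' under the next id for its locus (ids are append-only, starting at 1).
#' New fragments must match the locus's registered fragment length, and may
#' carry at most `max_ambig_frac` ambiguous (non-A/C/G/T) positions.
#'
#' @param db Allele database tibble ([new_allele_db()] or accumulated).
#' @param locus Locus name.
#' @param fragment Trimmed fragment sequence.
#' @param max_ambig_frac Maximum tolerated fraction of ambiguous bases.
#' @return List with `db` (updated database), `allele_id`, `is_new`, and
#'   `nearest` (for a new allele in a non-empty locus: tibble of the closest
#'   existing allele and its Hamming distance, else `NULL`).
#' @export
call_allele <- function(db, locus, fragment, max_ambig_frac = 0.02) {
  frag <- normalize_seq(fragment, allow_gap = FALSE)
  existing <- db[db$locus == locus, , drop = FALSE]
  if (nrow(existing) > 0) {
    reg_len <- nchar(existing$seq[1])
    if (nchar(frag) != reg_len) {
      abort(sprintf(
        "fragment length %d does not match the registered length %d for locus %s",
        nchar(frag), reg_len, locus))
    }
    hit <- existing$allele_id[existing$seq == frag]
    if (length(hit) > 0) {
      return(list(db = db, allele_id = hit[1], is_new = FALSE,
                  nearest = NULL))
    }
  }
  ambig <- mean(!(.seq_chars(frag) %in% c("A", "C", "G", "T")))
  if (ambig > max_ambig_frac) {
    abort(sprintf(
      "fragment has %.1f%% ambiguous bases (limit %.1f%%) for locus %s",
      100 * ambig, 100 * max_ambig_frac, locus))
  }
  new_id <- if (nrow(existing) == 0) 1L else max(existing$allele_id) + 1L
  nearest <- NULL
  if (nrow(existing) > 0) {
    d <- vapply(existing$seq, .hamming, integer(1), b = frag)
    i <- which.min(d)
    nearest <- tibble(allele_id = existing$allele_id[i],
                      hamming = unname(d[i]))
  }
  db <- bind_rows(db, tibble(locus = locus, allele_id = new_id, seq = frag))
  list(db = db, allele_id = new_id, is_new = TRUE, nearest = nearest)
}

#' Read or write an allele database as per-locus FASTA
#'
#' Headers follow the `locus_alleleID` convention. `write_allele_fasta()`
#' writes one combined FASTA; `read_allele_fasta()` parses it back. The
#' round trip is lossless.
#'
#' @param db Allele database tibble.
#' @param path FASTA path.
#' @return `read_allele_fasta()` returns the database tibble.
#' @export
write_allele_fasta <- function(db, path) {
  write_fasta(tibble(id = paste0(db$locus, "_", db$allele_id),
                     seq = db$seq), path)
}

#' @rdname write_allele_fasta
#' @export
read_allele_fasta <- function(path) {
  x <- read_fasta(path, allow_gap = FALSE)
  m <- regmatches(x$id, regexec("^(.*)_([0-9]+)$", x$id))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf("allele header '%s' is not of the form locus_alleleID",
                  x$id[bad][1]))
  }
  tibble(locus = vapply(m, `[[`, character(1), 2L),
         allele_id = as.integer(vapply(m, `[[`, character(1), 3L)),
         seq = x$seq)
}

#' Assign a sequence type to a complete allelic profile
#'
#' @param registry Tibble with column `st_id` plus one column per locus
#'   (zero rows to start), as produced by previous calls.
#' @param profile Named list or vector mapping locus to allele id; must
#'   cover every locus in `loci`.
#' @param loci Scheme loci defining completeness; defaults to the loci of
#'   the registry (or of the profile if the registry is empty).
#' @return List with `registry` (updated), `st_id`, `is_new`.
#' @export
assign_st <- function(registry, profile, loci = NULL) {
  profile <- unlist(profile)
  if (is.null(loci)) {
    loci <- if (nrow(registry) > 0) setdiff(names(registry), "st_id")
            else names(profile)
  }
  missing_loci <- setdiff(loci, names(profile)[!is.na(profile)])
  if (length(missing_loci) > 0) {
    abort(paste0("incomplete profile; missing locus/loci: ",
                 paste(missing_loci, collapse = ", ")))
  }
  prof_row <- as_tibble(as.list(profile[loci]))
  if (nrow(registry) > 0) {
    match_idx <- which(vapply(seq_len(nrow(registry)), function(i) {
      all(unlist(registry[i, loci]) == unlist(prof_row))
    }, logical(1)))
    if (length(match_idx) > 0) {
      return(list(registry = registry,
                  st_id = registry$st_id[match_idx[1]], is_new = FALSE))
    }
  }
  st_id <- if (nrow(registry) == 0) 1L else max(registry$st_id) + 1L
  registry <- bind_rows(registry, bind_cols(tibble(st_id = st_id), prof_row))
  list(registry = registry, st_id = st_id, is_new = TRUE)
}

#' Distance between two complete allelic profiles
#'
#' Number of loci at which the allele ids differ (0 to the number of scheme
#' loci). Both profiles must cover the same loci.
#'
#' @param p1,p2 Named lists or vectors mapping locus to allele id.
#' @return Non-negative integer.
#' @export
profile_distance <- function(p1, p2) {
  p1 <- unlist(p1); p2 <- unlist(p2)
  if (!setequal(names(p1), names(p2))) {
    abort("profiles cover different loci")
  }
  sum(p1[names(p1)] != p2[names(p1)])
}

#' Validate a strain label of the cXxxN convention
#'
#' Strain labels in the Cardinium literature follow `c` + a host
#' abbreviation + a serial number (e.g. `cEper1`). User labels are
#' free-form; this checks conformance without enforcing it.
#'
#' @param label Character vector of labels.
#' @return Logical vector.
#' @export
is_strain_label <- function(label) {
  grepl("^c[A-Z][A-Za-z]+[0-9]+$", label)
}
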