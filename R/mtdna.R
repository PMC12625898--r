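#' Construct a multiple sequence alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   over `A,C,G,T,N,-` (case-insensitive; other IUPAC ambiguity codes
#'   are treated as missing data by the statistics).
#' @return A `seq_alignment` object.
#' @export
seq_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))) || anyDuplicated(names(seqs))) {
    abort("Sequences must carry unique non-empty names.", class = "paleotrail_parse_error")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    abort("All aligned sequences must have the same length.", class = "paleotrail_parse_error")
  }
  structure(list(names = names(seqs), seqs = toupper(unname(seqs)),
                 length = unname(lens[1])),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d sequences x %d columns\n",
              length(x$names), x$length))
  cat("  ", paste(head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read/write alignments as FASTA
#'
#' Thin wrappers over Biostrings' FASTA support.
#'
#' @param path FASTA file.
#' @return `read_alignment_fasta()`: a `seq_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seq_alignment(setNames(as.character(ss), names(ss)))
}

#' @rdname read_alignment_fasta
#' @param aln A `seq_alignment`.
#' @return `write_alignment_fasta()`: `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  ss <- Biostrings::BStringSet(setNames(aln$seqs, aln$names))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Generate a synthetic alignment with planted substitutions
#'
#' Builds a random reference sequence plus `n_seqs - 1` derived
#' sequences, each carrying a known number of substitutions at positions
#' disjoint across sequences (so the pairwise difference between any two
#' derived sequences is the sum of their planted counts, and each
#' sequence differs from the reference by exactly its own count).
#' Optionally masks a fraction of sites per sequence to `N`, emulating
#' the patchy coverage of low-coverage ancient consensus sequences.
#'
#' @param n_seqs Total number of sequences including the reference.
#' @param length Alignment length, bases (default 16,600 — mitogenome
#'   scale).
#' @param planted_diffs Integer vector (recycled to `n_seqs - 1`) of
#'   substitution counts per derived sequence.
#' @param missing_frac Fraction of sites masked to `N` per sequence.
#' @param seed Integer seed.
#' @return A `seq_alignment` with sequences named `reference`,
#'   `seq_01`, ... and a `planted` attribute recording the truth.
#' @export
make_alignment <- function(n_seqs, length = 16600, planted_diffs = 0,
                           missing_frac = 0, seed = 1L) {
  stopifnot(n_seqs >= 1, length >= 1, missing_frac >= 0, missing_frac <= 1)
  n_derived <- n_seqs - 1L
  planted <- as.integer(rep_len(planted_diffs, max(n_derived, 0L)))
  if (sum(planted) > length) {
    abort(sprintf("Cannot plant %d disjoint substitutions in %d sites.",
                  sum(planted), length),
          class = "paleotrail_generation_error")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ref <- sample(bases, length, replace = TRUE)
    avail <- sample.int(length)  # shuffled site pool; consumed disjointly
    ptr <- 0L
    seqs <- character(n_seqs)
    seqs[1] <- paste(ref, collapse = "")
    for (i in seq_len(n_derived)) {
      s <- ref
      k <- planted[i]
      if (k > 0) {
        pos <- avail[ptr + seq_len(k)]
        ptr <- ptr + k
        s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), "")
      }
      seqs[i + 1L] <- paste(s, collapse = "")
    }
    if (missing_frac > 0) {
      n_mask <- floor(missing_frac * length)
      seqs <- vapply(seqs, function(sq) {
        ch <- strsplit(sq, "")[[1]]
        ch[sample.int(length, n_mask)] <- "N"
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    names(seqs) <- c("reference",
                     if (n_derived > 0) sprintf("seq_%02d", seq_len(n_derived)))
    out <- seq_alignment(seqs)
    attr(out, "planted") <- setNames(planted, names(seqs)[-1])
    out
  })
}

# Raw-byte view of one row; TRUE where the site is an unambiguous base.
aln_row_raw <- function(aln, label) {
  i <- match(label, aln$names)
  if (is.na(i)) {
    abort(sprintf("Sequence '%s' is not in the alignment.", label),
          class = "paleotrail_lookup_error")
  }
  charToRaw(aln$seqs[i])
}

BASE_RAW <- charToRaw("ACGT")

#' Pairwise nucleotide differences between two aligned sequences
#'
#' Counts differences over comparable sites only: alignment columns where
#' both sequences carry an unambiguous base (`A`, `C`, `G`, `T`). Gaps,
#' `N`, and other ambiguity codes are missing data, excluded from both
#' the numerator and the denominator.
#'
#' @param aln A `seq_alignment`.
#' @param a,b Sequence labels.
#' @return A one-row tibble: `seq_a`, `seq_b`, `n_diff`, `n_comparable`.
#' @examples
#' aln <- seq_alignment(c(x = "ACGN", y = "AC-T"))
#' pairwise_differences(aln, "x", "y")  # 0 differences over 2 comparable sites
#' @export
pairwise_differences <- function(aln, a, b) {
  stopifnot(inherits(aln, "seq_alignment"))
  ra <- aln_row_raw(aln, a)
  rb <- aln_row_raw(aln, b)
  ok <- (ra %in% BASE_RAW) & (rb %in% BASE_RAW)
  tibble::tibble(seq_a = a, seq_b = b,
                 n_diff = sum(ra[ok] != rb[ok]),
                 n_comparable = sum(ok))
}

#' Rank sequences by dissimilarity from a focal sequence
#'
#' Computes pairwise differences between the focal sequence and every
#' other row, sorted from most to least dissimilar (ties broken
#' lexicographically by sequence name for deterministic output).
#'
#' @param aln A `seq_alignment`.
#' @param focal Focal sequence label.
#' @return A tibble `seq_a, seq_b, n_diff, n_comparable`, one row per
#'   non-focal sequence, descending `n_diff`.
#' @export
rank_dissimilarity <- function(aln, focal) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (!focal %in% aln$names) {
    abort(sprintf("Sequence '%s' is not in the alignment.", focal),
          class = "paleotrail_lookup_error")
  }
  others <- setdiff(aln$names, focal)
  if (!length(others)) {
    return(tibble::tibble(seq_a = character(), seq_b = character(),
                          n_diff = integer(), n_comparable = integer()))
  }
  purrr::map_dfr(others, ~ pairwise_differences(aln, focal, .x)) |>
    dplyr::arrange(dplyr::desc(.data$n_diff), .data$seq_b)
}

#' Diagnostic-site read support for a derived lineage
#'
#' Tallies sequencing-read support at lineage-diagnostic positions
#' (sites where the derived allele of the target lineage differs from
#' the comparison population). `n_covered` counts reads overlapping
#' diagnostic positions with a called base (not `N`); `n_matching`
#' counts those equal to the derived allele.
#'
#' @param table A data frame with columns `position` (1-based),
#'   `derived_allele`, and `reads` — a list column of character vectors
#'   of observed read bases (or a comma-separated string).
#' @return A one-row tibble: `n_matching`, `n_covered`.
#' @export
diagnostic_allele_fraction <- function(table) {
  table <- tibble::as_tibble(table)
  if (!nrow(table)) return(tibble::tibble(n_matching = 0L, n_covered = 0L))
  if (!all(c("position", "derived_allele", "reads") %in% names(table))) {
    abort("Diagnostic table needs columns position, derived_allele, reads.",
          class = "paleotrail_parse_error")
  }
  if (any(table$position < 1)) {
    abort("Diagnostic positions are 1-based and must be >= 1.",
          class = "paleotrail_parse_error")
  }
  counts <- purrr::pmap(table, function(position, derived_allele, reads, ...) {
    reads <- if (is.character(reads) && length(reads) == 1L && grepl(",", reads)) {
      strsplit(reads, ",")[[1]]
    } else unlist(reads)
    reads <- toupper(trimws(reads))
    bad <- setdiff(reads, c("A", "C", "G", "T", "N"))
    if (length(bad)) {
      abort(sprintf("Unexpected read base(s) at position %d: %s",
                    position, paste(bad, collapse = ", ")),
            class = "paleotrail_parse_error")
    }
    covered <- reads != "N"
    c(matching = sum(covered & reads == toupper(derived_allele)),
      covered = sum(covered))
  })
  m <- do.call(rbind, counts)
  tibble::tibble(n_matching = as.integer(sum(m[, "matching"])),
                 n_covered = as.integer(sum(m[, "covered"])))
}
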