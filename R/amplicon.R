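#' Amplicon record tables
#'
#' The central data structure of chimbench is a plain tibble of amplicon
#' records, one row per read or dereplicated unique sequence, with columns:
#'
#' * `id` — character, unique within a dataset,
#' * `seq` — uppercase DNA over `A`, `C`, `G`, `T`, `N`,
#' * `abundance` — positive integer (defaults to 1; carries `;size=N`
#'   annotations after dereplication),
#' * `sample_id` — optional character,
#' * `quals` — optional list-column of integer Phred scores (0–93, the
#'   PacBio FASTQ dialect cap), one vector per read, same length as `seq`.
#'
#' Synthetic datasets additionally carry truth columns (`truth_class`,
#' `parent_ids`, `breakpoints`, `rc_segments`, `parent_starts`); see
#' [spike_dataset()].
#'
#' @param id Character vector of record ids.
#' @param seq Character vector of DNA sequences.
#' @param abundance Integer vector of abundances (recycled).
#' @param sample_id Optional character vector (recycled).
#' @param quals Optional list of integer Phred score vectors.
#' @return A tibble of amplicon records.
#' @examples
#' amplicon_tbl(c("s1", "s2"), c("ACGT", "GGTT"), abundance = c(3L, 1L))
#' @export
amplicon_tbl <- function(id, seq, abundance = 1L, sample_id = NA_character_,
                         quals = NULL) {
  x <- tibble(
    id = as.character(id),
    seq = toupper(as.character(seq)),
    abundance = as.integer(abundance),
    sample_id = as.character(sample_id)
  )
  if (!is.null(quals)) x$quals <- quals
  validate_amplicons(x)
}

#' Validate an amplicon table
#'
#' Checks the amplicon-table invariants: unique ids, non-empty sequences over
#' the `ACGTN` alphabet, abundances at least 1, and (when a `quals` column is
#' present) per-read quality vectors matching the sequence length with every
#' Phred score in 0–93.
#'
#' @param x A tibble of amplicon records.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_amplicons <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("id", "seq", "abundance") %in% names(x))) {
    abort("amplicon table needs columns id, seq, abundance")
  }
  if (anyDuplicated(x$id)) {
    dup <- x$id[duplicated(x$id)][1]
    abort(paste0("duplicate record id: ", dup))
  }
  if (any(!nzchar(x$seq))) abort("empty sequence in amplicon table")
  bad <- grepl("[^ACGTN]", x$seq)
  if (any(bad)) {
    abort(paste0("invalid characters in sequence of record ", x$id[which(bad)[1]]))
  }
  if (any(is.na(x$abundance)) || any(x$abundance < 1L)) {
    abort("abundances must be integers >= 1")
  }
  if ("quals" %in% names(x)) {
    ok <- purrr::map2_lgl(x$quals, nchar(x$seq), function(q, n) {
      is.null(q) || (length(q) == n && all(q >= 0L) && all(q <= 93L))
    })
    if (!all(ok)) {
      abort(paste0("quality vector of record ", x$id[which(!ok)[1]],
                   " does not match sequence length or exceeds Phred 93"))
    }
  }
  x
}

#' Reverse-complement DNA sequences
#'
#' Complement map A<->T, C<->G, N<->N. An involution: `revcomp(revcomp(s))`
#' is `s`.
#'
#' @param seq Character vector of DNA sequences over `ACGTN`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) abort("revcomp: invalid character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Expected errors of reads from Phred scores
#'
#' The maxEE statistic: for each read, the sum over bases of `10^(-Q/10)`,
#' i.e. the expected number of erroneous base calls.
#'
#' @param x Amplicon table with a `quals` list-column.
#' @return Numeric vector, one expected-error value per record.
#' @examples
#' x <- amplicon_tbl("r1", "ACGT", quals = list(rep(20L, 4)))
#' expected_errors(x) # 4 * 0.01
#' @export
expected_errors <- function(x) {
  if (!"quals" %in% names(x)) abort("expected_errors: records carry no quality scores")
  if (any(purrr::map_lgl(x$quals, is.null))) {
    abort("expected_errors: some records carry no quality scores")
  }
  purrr::map_dbl(x$quals, function(q) sum(10^(-q / 10)))
}

#' Filter reads by maximum expected errors
#'
#' Partitions the table into reads kept (expected errors `<= maxee`, boundary
#' inclusive) and discarded, preserving input order. Mirrors the
#' `--fastq_maxee` quality-filtering convention.
#'
#' @param x Amplicon table with a `quals` list-column.
#' @param maxee Maximum expected errors (default 1).
#' @return A list with tibbles `kept` and `discarded`.
#' @export
maxee_filter <- function(x, maxee = 1) {
  ee <- expected_errors(x)
  list(kept = x[ee <= maxee, , drop = FALSE],
       discarded = x[ee > maxee, , drop = FALSE])
}

#' Dereplicate identical sequences
#'
#' Collapses exact full-length string-identical sequences into one record with
#' summed abundance (`--derep_fulllength` semantics; no prefix clustering).
#' The representative id is the id of the highest-abundance member (ties go to
#' the lexicographically smallest id). Output is sorted by abundance
#' descending, ties by id. Total abundance is conserved.
#'
#' @param x Amplicon table.
#' @return A tibble `id`, `seq`, `abundance`, `n_members`, sorted by abundance
#'   descending; attribute `member_map` is a tibble mapping every input
#'   `member_id` to its `rep_id`.
#' @examples
#' x <- amplicon_tbl(c("a", "b", "c"), c("ACGT", "ACGT", "GGTT"))
#' dereplicate(x)
#' @export
dereplicate <- function(x) {
  validate_amplicons(x)
  reps <- x |>
    group_by(seq) |>
    summarise(
      rep_id = id[order(-abundance, id)][1],
      total = sum(abundance),
      n_members = dplyr::n(),
      members = list(id),
      .groups = "drop"
    )
  out <- tibble(
    id = reps$rep_id, seq = reps$seq,
    abundance = as.integer(reps$total), n_members = reps$n_members
  ) |>
    arrange(desc(abundance), id)
  attr(out, "member_map") <- tibble(
    member_id = unlist(reps$members),
    rep_id = rep(reps$rep_id, lengths(reps$members))
  )
  out
}
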