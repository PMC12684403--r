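#' Read a FASTA file into an amplicon table
#'
#' Understands the USEARCH/VSEARCH `;size=N` abundance annotation: with
#' `parse_size = TRUE` a trailing `;size=N` (optionally `;`-terminated) is
#' stripped from the header and stored as the record's abundance. Sequences
#' are uppercased; characters outside `ACGTN` are rejected.
#'
#' @param path Path to a FASTA file.
#' @param parse_size Parse `;size=N` annotations into abundances?
#' @return An amplicon tibble in file order.
#' @export
read_fasta <- function(path, parse_size = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr_at <- which(startsWith(lines, ">"))
  if (length(lines) && length(hdr_at) == 0) {
    abort(paste0(path, ": line 1: expected FASTA header"))
  }
  if (length(hdr_at) && hdr_at[1] != 1) {
    abort(paste0(path, ": line 1: expected FASTA header"))
  }
  ids <- character(0); seqs <- character(0); sizes <- integer(0)
  for (i in seq_along(hdr_at)) {
    h <- hdr_at[i]
    id <- sub("^>\\s*", "", lines[h])
    if (!nzchar(id)) abort(paste0(path, ": line ", h, ": malformed header"))
    to <- if (i < length(hdr_at)) hdr_at[i + 1] - 1 else length(lines)
    s <- toupper(paste0(lines[(h + 1):to][h + 1 <= to], collapse = ""))
    s <- gsub("\\s", "", s)
    if (!nzchar(s)) abort(paste0(path, ": line ", h, ": empty sequence"))
    size <- 1L
    if (parse_size && grepl(";size=\\d+;?$", id)) {
      size <- as.integer(sub("^.*;size=(\\d+);?$", "\\1", id))
      id <- sub(";size=\\d+;?$", "", id)
    }
    ids <- c(ids, id); seqs <- c(seqs, s); sizes <- c(sizes, size)
  }
  if (anyDuplicated(ids)) {
    abort(paste0(path, ": duplicate record id: ", ids[duplicated(ids)][1]))
  }
  amplicon_tbl(ids, seqs, abundance = sizes)
}

#' Write an amplicon table to FASTA
#'
#' With `with_size = TRUE`, headers carry the `;size=N` abundance annotation
#' so that [read_fasta()] with `parse_size = TRUE` round-trips id, sequence
#' and abundance exactly.
#'
#' @param x Amplicon table.
#' @param path Output path.
#' @param with_size Append `;size=N` to headers?
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, with_size = FALSE) {
  validate_amplicons(x)
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- if (with_size) paste0(x$id, ";size=", x$abundance) else x$id
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into an amplicon table
#'
#' Strict 4-line records. Quality characters are decoded as Phred+33; scores
#' above 93 (beyond the PacBio dialect cap) are clamped to 93 with a warning.
#'
#' @param path Path to a FASTQ file.
#' @return An amplicon tibble with a `quals` list-column.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(paste0(path, ": truncated FASTQ record near line ", length(lines)))
  }
  n <- length(lines) %/% 4
  if (n == 0) return(amplicon_tbl(character(0), character(0))[0, ])
  ids <- character(n); seqs <- character(n); quals <- vector("list", n)
  clamped <- FALSE
  for (i in seq_len(n)) {
    at <- (i - 1) * 4
    if (!startsWith(lines[at + 1], "@")) {
      abort(paste0(path, ": line ", at + 1, ": expected '@' header"))
    }
    ids[i] <- sub("^@\\s*", "", lines[at + 1])
    seqs[i] <- toupper(lines[at + 2])
    q <- utf8ToInt(lines[at + 4]) - 33L
    if (nchar(seqs[i]) != length(q)) {
      abort(paste0(path, ": line ", at + 4,
                   ": quality length differs from sequence length"))
    }
    if (any(q > 93L)) { clamped <- TRUE; q[q > 93L] <- 93L }
    quals[[i]] <- q
  }
  if (clamped) warn("Phred scores above 93 clamped to 93")
  if (anyDuplicated(ids)) {
    abort(paste0(path, ": duplicate record id: ", ids[duplicated(ids)][1]))
  }
  amplicon_tbl(ids, seqs, quals = quals)
}

#' Write an amplicon table to FASTQ (Phred+33)
#'
#' @param x Amplicon table with a `quals` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  validate_amplicons(x)
  if (!"quals" %in% names(x) || any(purrr::map_lgl(x$quals, is.null))) {
    abort("write_fastq: records carry no quality scores")
  }
  qstr <- purrr::map_chr(x$quals, function(q) intToUtf8(q + 33L))
  out <- character(4 * nrow(x))
  out[seq(1, length(out), 4)] <- paste0("@", x$id)
  out[seq(2, length(out), 4)] <- x$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qstr
  writeLines(out, path)
  invisible(path)
}

#' Read and write truth-label tables
#'
#' Truth labels record the ground-truth origin of every read in a synthetic
#' dataset: `klass` is one of `parental`, `pcr_chimera`, `concatemer`;
#' `parent_ids` lists the parent record ids (empty for parental);
#' `breakpoints` are cumulative segment lengths in the artifact (the k-th
#' breakpoint is the position of the last base of segment k, so an n-segment
#' artifact carries n-1 breakpoints, strictly increasing and interior);
#' `rc_segments` flags
#' reverse-complemented segments; `parent_starts` gives the 1-based start of
#' each segment within its parent, making every artifact exactly
#' reconstructable (see [reconstruct_artifact()]). List columns are serialized
#' comma-joined in the TSV.
#'
#' @param truth Truth tibble (`read_id`, `klass`, `parent_ids`, `breakpoints`,
#'   `rc_segments`, `parent_starts`).
#' @param path TSV path.
#' @return `read_truth_tsv()` returns the truth tibble with list columns;
#'   `write_truth_tsv()` returns `path` invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  flat <- tibble(
    read_id = truth$read_id,
    klass = truth$klass,
    parent_ids = purrr::map_chr(truth$parent_ids, paste, collapse = ","),
    breakpoints = purrr::map_chr(truth$breakpoints, paste, collapse = ","),
    rc_segments = purrr::map_chr(truth$rc_segments,
                                 function(v) paste(as.integer(v), collapse = ",")),
    parent_starts = purrr::map_chr(truth$parent_starts, paste, collapse = ",")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  split_int <- function(s) lapply(strsplit(ifelse(is.na(s), "", s), ","),
                                  function(v) as.integer(v[nzchar(v)]))
  split_chr <- function(s) lapply(strsplit(ifelse(is.na(s), "", s), ","),
                                  function(v) v[nzchar(v)])
  tibble(
    read_id = flat$read_id,
    klass = flat$klass,
    parent_ids = split_chr(flat$parent_ids),
    breakpoints = split_int(flat$breakpoints),
    rc_segments = lapply(split_int(flat$rc_segments), function(v) v == 1L),
    parent_starts = split_int(flat$parent_starts)
  )
}
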