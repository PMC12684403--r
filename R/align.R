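#' Alignment scoring parameters
#'
#' Default scoring mirrors the BLASTn costs commonly used for ITS validation
#' searches: reward +1, penalty -1, gap opening 1, gap extension 2 (a gap of
#' length L costs `gap_open + L * gap_extend`). `N` mismatches every base,
#' including another `N`.
#'
#' @param match Match reward (positive).
#' @param mismatch Mismatch penalty (negative).
#' @param gap_open Gap opening cost (non-negative).
#' @param gap_extend Per-base gap extension cost (non-negative).
#' @return A list of scoring parameters.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = 1, gap_extend = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps under [align_scoring()] costs. The
#' identity denominator is the number of alignment columns, gap columns
#' included (BLAST convention).
#'
#' @param a,b DNA sequences (single strings).
#' @param scoring An [align_scoring()] list.
#' @return A list: `score`, `identity_pct`, `columns`, and the gapped
#'   `aligned_a` / `aligned_b` strings (the column map).
#' @examples
#' align_global("ACGT", "ACCT")$identity_pct # 75
#' @export
align_global <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) abort("align_global: empty sequence")
  r <- .nw_align_one(a, b, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  list(score = r$score, identity_pct = r$identity_pct, columns = r$columns,
       aligned_a = r$aligned_a, aligned_b = r$aligned_b, match = r$match)
}

#' Semi-global alignment of a query against a target
#'
#' The query is aligned end-to-end with free end gaps on the target
#' ("glocal"); query coverage is therefore 100 by construction and identity
#' carries the signal. This is the alignment used by the false-positive
#' rescue rule.
#'
#' @param query,target DNA sequences (single strings).
#' @param scoring An [align_scoring()] list.
#' @return A list: `score`, `identity_pct`, `coverage_pct` (always 100),
#'   `columns`.
#' @export
align_semiglobal <- function(query, target, scoring = align_scoring()) {
  if (!nzchar(query) || !nzchar(target)) abort("align_semiglobal: empty sequence")
  r <- .sg_align_one(query, target, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  list(score = r$score, identity_pct = r$identity_pct,
       coverage_pct = 100, columns = r$columns)
}

# best local alignment of query[lo:hi] against target on one strand.
# returns NULL or a one-row hsp tibble in original query coordinates.
.local_hsp <- function(qseq, lo, hi, tseq, scoring, strand) {
  seg <- substr(qseq, lo, hi)
  if (strand == "-") seg <- revcomp(seg)
  r <- .sw_align_one(seg, tseq, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  if (r$score <= 0) return(NULL)
  if (strand == "+") {
    q_start <- lo + r$q_start - 1L; q_end <- lo + r$q_end - 1L
  } else {
    q_start <- hi - r$q_end + 1L; q_end <- hi - r$q_start + 1L
  }
  tibble(
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    t_start = r$t_start, t_end = r$t_end,
    score = r$score, identity_pct = r$identity_pct, strand = strand
  )
}

#' Multi-HSP local alignment of a query against a target
#'
#' Emulates the multiple high-scoring segment pairs (HSPs) a BLASTn report
#' lists per hit: iteratively finds the best local alignment (both strands
#' unless `both_strands = FALSE`), records it, masks its query interval, and
#' repeats until `max_hsps` is reached or the best remaining score drops
#' below `min_hsp_score`. HSP query intervals are pairwise non-overlapping by
#' construction; the "first HSP" is the highest-scoring one. Coordinates are
#' 1-based inclusive.
#'
#' @param query,target DNA sequences (single strings).
#' @param scoring An [align_scoring()] list.
#' @param max_hsps Maximum number of HSPs to report.
#' @param min_hsp_score Minimum score for an HSP to be kept.
#' @param both_strands Search the reverse strand too?
#' @param query_id,target_id Optional ids carried into the result.
#' @return A list with `query_id`, `target_id`, `hsps` (tibble sorted by
#'   score descending, with per-HSP `query_coverage_pct`), `total_score`,
#'   `best_identity_pct`, `query_coverage_pct` (of the first HSP), and
#'   `n_hsps`. `n_hsps == 0` signals "no hit".
#' @export
find_hsps <- function(query, target, scoring = align_scoring(),
                      max_hsps = 4L, min_hsp_score = 30,
                      both_strands = TRUE,
                      query_id = NA_character_, target_id = NA_character_) {
  if (!nzchar(query) || !nzchar(target)) abort("find_hsps: empty sequence")
  stopifnot(max_hsps >= 1)
  qlen <- nchar(query)
  intervals <- list(c(1L, qlen))
  hsps <- list()
  while (length(hsps) < max_hsps && length(intervals) > 0) {
    best <- NULL; best_at <- NA_integer_
    for (i in seq_along(intervals)) {
      iv <- intervals[[i]]
      if (iv[2] - iv[1] + 1L < 5L) next
      for (strand in if (both_strands) c("+", "-") else "+") {
        h <- .local_hsp(query, iv[1], iv[2], target, scoring, strand)
        if (!is.null(h) && (is.null(best) || h$score > best$score)) {
          best <- h; best_at <- i
        }
      }
    }
    if (is.null(best) || best$score < min_hsp_score) break
    hsps[[length(hsps) + 1]] <- best
    iv <- intervals[[best_at]]
    intervals[[best_at]] <- NULL
    if (best$q_start - 1L >= iv[1]) {
      intervals[[length(intervals) + 1]] <- c(iv[1], best$q_start - 1L)
    }
    if (best$q_end + 1L <= iv[2]) {
      intervals[[length(intervals) + 1]] <- c(best$q_end + 1L, iv[2])
    }
  }
  hs <- if (length(hsps)) bind_rows(hsps) |> arrange(desc(score)) else
    tibble(q_start = integer(0), q_end = integer(0), t_start = integer(0),
           t_end = integer(0), score = numeric(0), identity_pct = numeric(0),
           strand = character(0))
  hs$query_coverage_pct <- if (nrow(hs)) 100 * (hs$q_end - hs$q_start + 1L) / qlen else numeric(0)
  list(
    query_id = query_id, target_id = target_id, hsps = hs,
    total_score = sum(hs$score), n_hsps = nrow(hs),
    best_identity_pct = if (nrow(hs)) hs$identity_pct[1] else NA_real_,
    query_coverage_pct = if (nrow(hs)) hs$query_coverage_pct[1] else NA_real_
  )
}

# sparse kmer-presence matrix: 4^k rows (2-bit encoded kmers) x length(seqs)
.kmer_matrix <- function(seqs, k = 8L) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  ii <- list(); jj <- list()
  for (j in seq_along(seqs)) {
    v <- code[strsplit(seqs[j], "")[[1]]]  # N -> NA, poisons overlapping kmers
    n <- length(v)
    if (n < k) next
    idx <- v[1:(n - k + 1)]
    ok <- !is.na(idx)
    for (off in 1:(k - 1)) {
      nxt <- v[(1 + off):(n - k + 1 + off)]
      idx <- idx * 4L + nxt
      ok <- ok & !is.na(nxt)
    }
    km <- unique(idx[ok])
    ii[[length(ii) + 1]] <- km + 1L
    jj[[length(jj) + 1]] <- rep(j, length(km))
  }
  Matrix::sparseMatrix(
    i = unlist(ii) %||% integer(0), j = unlist(jj) %||% integer(0), x = 1,
    dims = c(4L^k, length(seqs))
  )
}

# shared-kmer counts: columns of `a` vs columns of `b` -> dense matrix
.shared_kmers <- function(a, b) as.matrix(Matrix::crossprod(a, b))

#' Best database hit for a query
#'
#' Scans a database of amplicon records and returns the hit with maximal
#' total score (ties broken by larger best identity, then lexicographic
#' target id). `mode = "hsps"` uses multi-HSP local alignment (the
#' false-negative rule's search); `mode = "semiglobal"` aligns the query
#' end-to-end (the false-positive rescue search). With `exclude_self`,
#' targets whose id equals the query id are skipped. `prescreen` limits full
#' alignment to the top-N targets by shared 8-mer count (0 disables
#' prescreening and scans every target).
#'
#' @param query One-row amplicon tibble (or a list with `id` and `seq`).
#' @param db Amplicon table to search.
#' @param scoring An [align_scoring()] list.
#' @param mode `"hsps"` or `"semiglobal"`.
#' @param exclude_self Skip targets with the query's id?
#' @param prescreen Number of kmer-prescreened targets to align (0 = all).
#' @param db_kmers Optional prebuilt kmer index of `db` (internal reuse
#'   across many queries; see [flag_false_negatives()]).
#' @param ... Passed to [find_hsps()] (e.g. `max_hsps`, `min_hsp_score`).
#' @return A [find_hsps()]-style hit list (for `"semiglobal"`, a single
#'   synthetic HSP covering the query), or `NULL` when there is no hit.
#' @export
best_hit <- function(query, db, scoring = align_scoring(),
                     mode = c("hsps", "semiglobal"),
                     exclude_self = TRUE, prescreen = 8L, db_kmers = NULL, ...) {
  mode <- match.arg(mode)
  if (nrow(db) == 0) abort("best_hit: empty database")
  qid <- query$id[[1]]; qseq <- query$seq[[1]]
  keep <- if (exclude_self) db$id != qid else rep(TRUE, nrow(db))
  if (!any(keep)) return(NULL)
  if (prescreen > 0 && sum(keep) > prescreen) {
    if (is.null(db_kmers)) db_kmers <- .kmer_matrix(db$seq)
    shared <- .shared_kmers(.kmer_matrix(qseq), db_kmers)[1, ]
    shared <- shared[keep]
    db <- db[keep, , drop = FALSE]
    ord <- order(-shared, db$id)
    db <- db[ord[seq_len(prescreen)], , drop = FALSE]
  } else {
    db <- db[keep, , drop = FALSE]
  }
  best <- NULL
  for (i in order(db$id)) {
    hit <- if (mode == "hsps") {
      find_hsps(qseq, db$seq[i], scoring, query_id = qid,
                target_id = db$id[i], ...)
    } else {
      sg <- align_semiglobal(qseq, db$seq[i], scoring)
      list(query_id = qid, target_id = db$id[i],
           hsps = tibble(q_start = 1L, q_end = nchar(qseq), t_start = NA_integer_,
                         t_end = NA_integer_, score = sg$score,
                         identity_pct = sg$identity_pct, strand = "+",
                         query_coverage_pct = 100),
           total_score = sg$score, n_hsps = 1L,
           best_identity_pct = sg$identity_pct, query_coverage_pct = 100)
    }
    if (hit$n_hsps == 0) next
    if (is.null(best) ||
        hit$total_score > best$total_score ||
        (hit$total_score == best$total_score &&
         hit$best_identity_pct > best$best_identity_pct)) {
      best <- hit
    }
  }
  best
}

#' Export hits as BLAST outfmt-6-like rows
#'
#' @param hits A list of [find_hsps()]/[best_hit()] results.
#' @return A tibble with columns qseqid, sseqid, pident, length, qstart,
#'   qend, sstart, send, score, qcovhsp (one row per HSP).
#' @export
hits_to_blast6 <- function(hits) {
  purrr::map_dfr(hits, function(h) {
    if (is.null(h) || h$n_hsps == 0) return(NULL)
    tibble(
      qseqid = h$query_id, sseqid = h$target_id,
      pident = round(h$hsps$identity_pct, 3),
      length = h$hsps$q_end - h$hsps$q_start + 1L,
      qstart = h$hsps$q_start, qend = h$hsps$q_end,
      sstart = h$hsps$t_start, send = h$hsps$t_end,
      score = h$hsps$score, qcovhsp = round(h$hsps$query_coverage_pct, 3)
    )
  })
}
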