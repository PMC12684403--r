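#' Secondary-validation configuration
#'
#' Thresholds for the reference-based validation of detector output:
#' false-positive rescue (a flagged read with best reference identity and
#' query coverage both at least 99% is a genuine sequence, not a chimera),
#' false-negative flagging (a retained read whose best non-self hit splits
#' into at least `min_hsps_for_fn` HSPs with the highest-scoring HSP
#' covering under 85% of the query is a chimera that slipped through), and
#' 5.8S counting (local hits of a 5.8S model at `r58s_id_min_pct` identity
#' covering at least `r58s_cov_min_frac` of the model; a genuine ITS read
#' carries exactly one, a k-amplicon concatemer carries k).
#'
#' @param id_min_pct Rescue identity threshold, percent (inclusive).
#' @param cov_min_pct Rescue query-coverage threshold, percent (inclusive).
#' @param hsp_cov_max_pct First-HSP coverage below which a multi-HSP hit
#'   marks a chimera (exclusive bound).
#' @param min_hsps_for_fn Minimum HSPs per best hit for the FN rule.
#' @param r58s_model 5.8S model sequence (e.g. the community consensus from
#'   [make_templates()]).
#' @param r58s_id_min_pct Identity threshold for a 5.8S hit, percent.
#' @param r58s_cov_min_frac Minimum fraction of the model covered.
#' @return A `validation_config` list.
#' @export
validation_config <- function(id_min_pct = 99, cov_min_pct = 99,
                              hsp_cov_max_pct = 85, min_hsps_for_fn = 2L,
                              r58s_model = NULL, r58s_id_min_pct = 85,
                              r58s_cov_min_frac = 0.8) {
  stopifnot(id_min_pct > 0, id_min_pct <= 100, cov_min_pct > 0,
            cov_min_pct <= 100, hsp_cov_max_pct > 0, hsp_cov_max_pct <= 100,
            min_hsps_for_fn >= 1, r58s_id_min_pct > 0, r58s_id_min_pct <= 100,
            r58s_cov_min_frac > 0, r58s_cov_min_frac <= 1)
  structure(list(
    id_min_pct = id_min_pct, cov_min_pct = cov_min_pct,
    hsp_cov_max_pct = hsp_cov_max_pct,
    min_hsps_for_fn = as.integer(min_hsps_for_fn),
    r58s_model = r58s_model, r58s_id_min_pct = r58s_id_min_pct,
    r58s_cov_min_frac = r58s_cov_min_frac
  ), class = "validation_config")
}

#' Rescue false-positive chimeras by reference alignment
#'
#' Every flagged read is aligned semi-globally against the reference
#' database; a read whose best hit reaches both thresholds (inclusive) is a
#' genuine biological sequence wrongly flagged (`fp_rescued`), everything
#' else remains a `true_chimera`.
#'
#' @param flagged Amplicon table of reads the detector flagged as chimeric.
#' @param reference_db Amplicon table of reference sequences.
#' @param config A [validation_config()].
#' @param scoring An [align_scoring()] list.
#' @return A tibble: `read_id`, `verdict`, `best_target`, `identity_pct`,
#'   `coverage_pct`.
#' @export
rescue_false_positives <- function(flagged, reference_db,
                                   config = validation_config(),
                                   scoring = align_scoring()) {
  if (nrow(reference_db) == 0) abort("rescue_false_positives: empty reference")
  purrr::map_dfr(seq_len(nrow(flagged)), function(i) {
    hit <- best_hit(flagged[i, ], reference_db, scoring, mode = "semiglobal",
                    exclude_self = FALSE)
    rescued <- !is.null(hit) &&
      hit$best_identity_pct >= config$id_min_pct &&
      hit$query_coverage_pct >= config$cov_min_pct
    tibble(
      read_id = flagged$id[i],
      verdict = if (rescued) "fp_rescued" else "true_chimera",
      best_target = if (is.null(hit)) NA_character_ else hit$target_id,
      identity_pct = if (is.null(hit)) NA_real_ else hit$best_identity_pct,
      coverage_pct = if (is.null(hit)) NA_real_ else hit$query_coverage_pct
    )
  })
}

#' Flag false-negative chimeras in the retained set
#'
#' Each retained read is searched (multi-HSP local alignment) against the
#' union of the sample's own reads and the reference database, excluding
#' self-hits by id. A read is `fn_chimera` when its best hit has at least
#' `min_hsps_for_fn` HSPs and the highest-scoring ("first") HSP covers less
#' than `hsp_cov_max_pct` of the query; otherwise `non_chimera`. Reads with
#' no non-self hit are `non_chimera`.
#'
#' @param retained Amplicon table of reads that passed chimera filtering.
#' @param sample_db Amplicon table of reads from the same sample (typically
#'   the retained set itself; self-hits are excluded by id).
#' @param reference_db Amplicon table of reference sequences.
#' @param config A [validation_config()].
#' @param scoring An [align_scoring()] list.
#' @param max_hsps,min_hsp_score Passed to [find_hsps()].
#' @return A tibble: `read_id`, `verdict`, `best_target`, `n_hsps`,
#'   `first_hsp_cov_pct`.
#' @export
flag_false_negatives <- function(retained, sample_db, reference_db,
                                 config = validation_config(),
                                 scoring = align_scoring(),
                                 max_hsps = 4L, min_hsp_score = 30) {
  db <- bind_rows(
    sample_db[, c("id", "seq")],
    reference_db[, c("id", "seq")]
  )
  db <- db[!duplicated(db$id), ]
  db_kmers <- .kmer_matrix(db$seq)
  purrr::map_dfr(seq_len(nrow(retained)), function(i) {
    hit <- best_hit(retained[i, ], db, scoring, mode = "hsps",
                    exclude_self = TRUE, max_hsps = max_hsps,
                    min_hsp_score = min_hsp_score, db_kmers = db_kmers)
    is_fn <- !is.null(hit) &&
      hit$n_hsps >= config$min_hsps_for_fn &&
      hit$query_coverage_pct < config$hsp_cov_max_pct
    tibble(
      read_id = retained$id[i],
      verdict = if (is_fn) "fn_chimera" else "non_chimera",
      best_target = if (is.null(hit)) NA_character_ else hit$target_id,
      n_hsps = if (is.null(hit)) 0L else hit$n_hsps,
      first_hsp_cov_pct = if (is.null(hit)) NA_real_ else hit$query_coverage_pct
    )
  })
}

#' Count 5.8S copies in reads
#'
#' Greedy non-overlapping local alignment of the 5.8S model against each
#' read; hits count when they reach `r58s_id_min_pct` identity and cover at
#' least `r58s_cov_min_frac` of the model. A genuine full-ITS read contains
#' exactly one 5.8S gene; two or more mark a likely concatemer.
#'
#' @param reads Amplicon table.
#' @param config A [validation_config()] with `r58s_model` set.
#' @param scoring An [align_scoring()] list.
#' @return `reads` with an integer `n_58s` column appended.
#' @export
count_58s <- function(reads, config, scoring = align_scoring()) {
  model <- config$r58s_model
  if (is.null(model)) abort("count_58s: config$r58s_model is not set")
  mlen <- nchar(model)
  min_sc <- max(20, floor(0.25 * mlen))
  n <- purrr::map_int(reads$seq, function(s) {
    hit <- find_hsps(s, model, scoring, max_hsps = 8L, min_hsp_score = min_sc,
                     both_strands = FALSE)
    if (hit$n_hsps == 0) return(0L)
    ok <- hit$hsps$identity_pct >= config$r58s_id_min_pct &
      (hit$hsps$t_end - hit$hsps$t_start + 1L) / mlen >= config$r58s_cov_min_frac
    sum(ok)
  })
  reads$n_58s <- n
  reads
}

#' Structure report for false-negative chimeras
#'
#' Summarizes 5.8S multiplicity and length for a set of false-negative
#' reads: the fraction carrying two or more 5.8S copies, and median lengths
#' stratified by multiplicity (concatemer-like reads are markedly longer).
#'
#' @param fn_reads Amplicon table of false-negative reads. If it carries no
#'   `n_58s` column, [count_58s()] is run with `config`.
#' @param config A [validation_config()] (only needed to compute `n_58s`).
#' @param scoring An [align_scoring()] list.
#' @return A list: `per_read` tibble (`read_id`, `length_bp`, `n_58s`) and
#'   `summary` one-row tibble (`n`, `n_multi_58s`, `frac_multi_58s`,
#'   `median_len_multi`, `median_len_single`).
#' @export
fn_structure_report <- function(fn_reads, config = NULL,
                                scoring = align_scoring()) {
  if (nrow(fn_reads) == 0) {
    return(list(
      per_read = tibble(read_id = character(0), length_bp = integer(0),
                        n_58s = integer(0)),
      summary = tibble(n = 0L, n_multi_58s = 0L, frac_multi_58s = NA_real_,
                       median_len_multi = NA_real_, median_len_single = NA_real_)
    ))
  }
  if (!"n_58s" %in% names(fn_reads)) {
    if (is.null(config)) abort("fn_structure_report: need n_58s or a config")
    fn_reads <- count_58s(fn_reads, config, scoring)
  }
  per_read <- tibble(read_id = fn_reads$id, length_bp = nchar(fn_reads$seq),
                     n_58s = fn_reads$n_58s)
  multi <- per_read$n_58s >= 2L
  summary <- tibble(
    n = nrow(per_read), n_multi_58s = sum(multi),
    frac_multi_58s = mean(multi),
    median_len_multi = if (any(multi)) median(per_read$length_bp[multi]) else NA_real_,
    median_len_single = if (any(!multi)) median(per_read$length_bp[!multi]) else NA_real_
  )
  list(per_read = per_read, summary = summary)
}
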