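#' Detector parameters
#'
#' A single engine exposes both parameter families used by de novo
#' chimera detectors on dereplicated amplicons:
#'
#' * `abskew` — minimum abundance ratio a candidate parent must have over the
#'   query (higher = fewer testable queries, more specificity),
#' * `minh` — threshold on the chimera evidence score h (smaller = more
#'   sensitive),
#' * `mindiffs` — minimum "yes" votes required in every query segment,
#' * `dn` — pseudo-count weight on abstain votes (higher = more specific),
#' * `xn` — weight on "no" votes,
#' * `mindiv` — minimum divergence (percent) of the query from its closest
#'   candidate parent; queries nearly identical to a parent are never called,
#' * `parts` — number of segments the query may be divided into (2 or 3),
#' * `min_segment_len` — minimum segment length considered,
#' * `max_diff_pct` — maximum percent mismatch allowed between query and its
#'   chimeric model (`Inf` disables the gate),
#' * `top_candidates` — candidate parents retained after shared-kmer pruning,
#' * `kmer` — kmer size for candidate pruning,
#' * `both_strands` — also consider reverse-complemented parent segments
#'   (off by default; breakpoint detectors classically miss
#'   reverse-complement-segment chimeras, and the default reproduces that).
#'
#' `preset = "uchime"` gives the classic short-read defaults (`abskew = 2`);
#' `preset = "chimeras_denovo"` the long-read family defaults (`abskew = 1`).
#'
#' @param abskew,minh,mindiffs,dn,xn,mindiv,parts,min_segment_len,max_diff_pct,top_candidates,kmer,both_strands
#'   See above.
#' @param preset Optional preset name applied before explicit arguments.
#' @return A `detector_params` list.
#' @export
detector_params <- function(abskew = 2, minh = 0.28, mindiffs = 3L, dn = 1.4,
                            xn = 2, mindiv = 0.8, parts = 2L,
                            min_segment_len = 10L, max_diff_pct = Inf,
                            top_candidates = 4L, kmer = 8L,
                            both_strands = FALSE, preset = NULL) {
  p <- list(abskew = abskew, minh = minh, mindiffs = as.integer(mindiffs),
            dn = dn, xn = xn, mindiv = mindiv, parts = as.integer(parts),
            min_segment_len = as.integer(min_segment_len),
            max_diff_pct = max_diff_pct,
            top_candidates = as.integer(top_candidates),
            kmer = as.integer(kmer), both_strands = both_strands)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("uchime", "chimeras_denovo"))
    if (preset == "chimeras_denovo" && missing(abskew)) p$abskew <- 1
  }
  stopifnot(p$abskew >= 1, p$minh > 0, p$minh <= 1, p$mindiffs >= 0,
            p$dn >= 0, p$xn >= 1, p$mindiv >= 0, p$parts %in% c(2L, 3L),
            p$min_segment_len >= 1, p$max_diff_pct >= 0,
            p$top_candidates >= 1, p$kmer >= 3)
  structure(p, class = "detector_params")
}

# batch global alignments of several queries against one target; returns, per
# query, the per-query-position match logical and column identity
.global_match_vectors <- function(qseqs, tseq, scoring) {
  .nw_match_batch(qseqs, tseq, scoring$match, scoring$mismatch,
                  scoring$gap_open, scoring$gap_extend)
}

# match vector of a query against the reverse complement of a candidate.
# a reverse-complemented segment sits at an arbitrary offset, so a local
# alignment (mapped back onto query positions) is the right construction;
# positions outside the aligned block never match.
.rc_match_vector <- function(qseq, tseq, scoring) {
  r <- .sw_align_one(qseq, revcomp(tseq), scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  list(match = r$match, identity_pct = 100 * sum(r$match) / nchar(qseq))
}

# segment vote counts for a model: parents = indices into mvecs per segment,
# bounds = segment end positions (last = L)
.model_votes <- function(mvecs, parents, bounds) {
  L <- bounds[length(bounds)]
  starts <- c(1L, head(bounds, -1) + 1L)
  uniq <- unique(parents)
  y <- n <- a <- integer(length(parents))
  seg_ident <- numeric(length(parents))
  for (s in seq_along(parents)) {
    rng <- starts[s]:bounds[s]
    mp <- mvecs[[parents[s]]][rng]
    others <- setdiff(uniq, parents[s])
    mo <- rep(FALSE, length(rng))
    for (o in others) mo <- mo | mvecs[[o]][rng]
    y[s] <- sum(mp & !mo)
    n[s] <- sum(!mp & mo)
    a[s] <- sum(!mp & !mo)
    seg_ident[s] <- 100 * sum(mp) / length(rng)
  }
  list(y = y, n = n, a = a, seg_ident = seg_ident)
}

# evidence -> verdict under threshold-type params; evidence is a one-row list.
# a model is only admissible when it explains the query at least `mindiv`
# percentage points better than the best single candidate does (model_gain_pp);
# without that margin a 1-2 match alignment-noise "improvement" over the true
# parent would let ordinary noisy reads through as borderline calls
.call_verdict <- function(has_model, y_total, n_total, a_total, y_min,
                          div_pct, model_diff_pct, model_gain_pp,
                          seg_ident_min, params) {
  denom <- y_total + params$xn * n_total + params$dn * a_total
  h <- ifelse(has_model & denom > 0, y_total / denom, 0)
  # every segment must derive from its model parent: a segment matching its
  # parent on no more than half its positions (unrelated DNA matches ~25%,
  # e.g. a reverse-complemented fragment) is no evidence of parenthood
  g_seg <- !is.na(seg_ident_min) & seg_ident_min > 50
  g_gain <- has_model & g_seg & model_gain_pp >= params$mindiv
  g_h <- g_gain & h >= params$minh
  g_md <- y_min >= params$mindiffs
  g_dv <- div_pct >= params$mindiv
  g_df <- model_diff_pct <= params$max_diff_pct
  verdict <- ifelse(
    g_h & g_md & g_dv & g_df & !is.na(g_md), "chimera",
    ifelse(g_h & g_df & xor(!g_md, !g_dv) & !is.na(g_md), "borderline", "clean")
  )
  verdict[is.na(verdict)] <- "clean"
  list(verdict = verdict, h = h)
}

# model comparator: larger score wins; ties -> larger total Y, then
# lexicographically smaller parent-id key
.better_model <- function(cand, best) {
  if (is.null(best)) return(TRUE)
  if (cand$score != best$score) return(cand$score > best$score)
  if (cand$y_total != best$y_total) return(cand$y_total > best$y_total)
  cand$key < best$key
}

# evaluate all chimeric models for one query; mvecs: list of per-candidate
# match vectors (query positions) for the abskew-gated model candidates; ids:
# their ids (orientation-expanded entries share the base id). ref_best_matches
# and ref_div_pct summarize the abskew-independent reference neighbours (the
# closest records at least as abundant as the query): a model must beat
# ref_best_matches, and div_pct is measured against that same fixed set, so
# raising abskew can only shrink the model search, never the yardstick.
.evaluate_query <- function(mvecs, ids, ref_best_matches, ref_div_pct, params) {
  ev <- list(has_model = FALSE, parents = character(0), breakpoints = integer(0),
             y_total = NA_integer_, n_total = NA_integer_, a_total = NA_integer_,
             y_min = NA_integer_, div_pct = ref_div_pct,
             model_diff_pct = NA_real_, model_gain_pp = NA_real_,
             seg_ident_min = NA_real_,
             model_score = NA_real_, best_single_score = ref_best_matches)
  if (length(mvecs) == 0) return(ev)
  L <- length(mvecs[[1]]$match)
  minseg <- params$min_segment_len
  m <- lapply(mvecs, `[[`, "match")
  S <- vapply(m, sum, numeric(1))
  if (L < 2L * minseg) return(ev)
  P <- lapply(m, cumsum)
  ord <- order(ids)
  tied <- list(); best_score <- -Inf
  push <- function(score, parents, bounds) {
    if (score > best_score) { best_score <<- score; tied <<- list() }
    if (score == best_score) {
      tied[[length(tied) + 1]] <<- list(parents = parents, bounds = bounds)
    }
  }
  brange <- minseg:(L - minseg)
  for (i in ord) for (j in ord) {
    if (ids[i] == ids[j]) next
    sc <- P[[i]][brange] + S[j] - P[[j]][brange]
    b <- brange[which.max(sc)]
    push(max(sc), c(i, j), c(b, L))
  }
  if (params$parts == 3L && L >= 3L * minseg && length(unique(ids)) >= 2) {
    b2range <- (2L * minseg):(L - minseg)
    for (i in ord) for (j in ord) {
      if (ids[i] == ids[j]) next
      D <- P[[i]] - P[[j]]
      # running max of D[b1] over b1 <= b2 - minseg, tracking earliest argmax
      b1cand <- minseg:(L - 2L * minseg)
      rm_val <- cummax(D[b1cand])
      improved <- D[b1cand] > c(-Inf, head(rm_val, -1))
      rm_arg <- b1cand[cummax(seq_along(b1cand) * improved)]
      for (k in ord) {
        if (ids[k] == ids[j]) next
        tot <- rm_val + P[[j]][b2range] + S[k] - P[[k]][b2range]
        at <- which.max(tot)
        push(max(tot), c(i, j, k), c(rm_arg[at], b2range[at], L))
      }
    }
  }
  if (best_score <= ev$best_single_score) return(ev)
  best <- NULL
  for (cand in tied) {
    v <- .model_votes(m, cand$parents, cand$bounds)
    entry <- list(score = best_score, y_total = sum(v$y),
                  key = paste(ids[cand$parents], collapse = "\r"),
                  parents = cand$parents, bounds = cand$bounds, votes = v)
    if (.better_model(entry, best)) best <- entry
  }
  ev$has_model <- TRUE
  ev$parents <- ids[best$parents]
  ev$breakpoints <- head(best$bounds, -1)
  ev$y_total <- sum(best$votes$y); ev$n_total <- sum(best$votes$n)
  ev$a_total <- sum(best$votes$a); ev$y_min <- min(best$votes$y)
  ev$seg_ident_min <- min(best$votes$seg_ident)
  ev$model_score <- best_score
  ev$model_diff_pct <- 100 * (L - best_score) / L
  ev$model_gain_pp <- 100 * (best_score - ev$best_single_score) / L
  ev
}

#' De novo chimera detection with UCHIME-style vote scoring
#'
#' Each query is judged against two sets of neighbours found by shared-kmer
#' ranking (`top_candidates` each):
#'
#' * the *reference* neighbours — the closest records strictly more abundant
#'   than the query, independent of `abskew`. They set the yardstick: the
#'   best single-candidate explanation of the query (`best_single_score`)
#'   and the query's divergence from its closest candidate (`div_pct`).
#' * the *model* candidates — records with abundance at least
#'   `abskew` times the query's, the only ones allowed to act as parents.
#'
#' Each candidate is mapped onto the query by optimal global alignment; for
#' every ordered candidate pair (and, with `parts = 3`, ordered triple) the
#' breakpoints maximizing the total number of query-model matches are found.
#' A chimeric model is admissible only when it explains the query at least
#' `mindiv` percentage points better than the best single reference
#' candidate (`model_gain_pp >= mindiv`) — a model that merely ties the best
#' parent within alignment noise is no evidence of chimerism. Query
#' positions then vote per segment: Y (matches the model parent and not the
#' others), N (matches another model parent instead), A (matches none); the
#' evidence score is `h = sum(Y) / (sum(Y) + xn * sum(N) + dn * sum(A))`.
#'
#' The verdict is `chimera` when the model is admissible, `h >= minh`, every
#' segment has at least `mindiffs` Y votes, `div_pct >= mindiv`, and the
#' query-model mismatch is at most `max_diff_pct`; `borderline` when the
#' model is admissible, `h >= minh` and exactly one of the mindiffs /
#' mindiv gates fails; otherwise `clean`. Because raising `abskew` only
#' shrinks the model candidate set while the reference yardstick stays
#' fixed, the chimera count is (near-)monotone non-increasing in `abskew`.
#'
#' @param records Dereplicated amplicon table (ids, seqs, abundances).
#' @param params A [detector_params()].
#' @param scoring An [align_scoring()] list.
#' @return A calls tibble: `query_id`, `verdict`, `h`, list-columns
#'   `parents` and `breakpoints`, vote totals, `y_min`, `div_pct`,
#'   `model_diff_pct`, `model_gain_pp`, `model_score`, `best_single_score`.
#'   The params used are stored in attribute `params`.
#' @export
detect_chimeras <- function(records, params = detector_params(),
                            scoring = align_scoring()) {
  validate_amplicons(records)
  if (anyDuplicated(records$seq)) {
    warn("detect_chimeras: input contains duplicate sequences; dereplicate first")
  }
  n <- nrow(records)
  empty_ev <- list(has_model = FALSE, parents = character(0),
                   breakpoints = integer(0), y_total = NA_integer_,
                   n_total = NA_integer_, a_total = NA_integer_,
                   y_min = NA_integer_, div_pct = NA_real_,
                   model_diff_pct = NA_real_, model_gain_pp = NA_real_,
                   seg_ident_min = NA_real_,
                   model_score = NA_real_, best_single_score = NA_real_)
  if (n == 0) return(.calls_tibble(character(0), list(), params))
  records <- records |> arrange(desc(abundance), id)
  ab <- records$abundance
  evidence <- rep(list(empty_ev), n)
  if (n > 1) {
    K <- .kmer_matrix(records$seq, params$kmer)
    topk <- function(idx, sh) {
      ord <- order(-sh, -ab[idx], records$id[idx])
      idx[ord[seq_len(min(params$top_candidates, length(idx)))]]
    }
    ref_sets <- vector("list", n)   # abskew-independent reference neighbours
    mod_sets <- vector("list", n)   # abskew-gated model candidates
    blk <- 512L
    for (lo in seq(1L, n, by = blk)) {
      qs <- lo:min(lo + blk - 1L, n)
      shared <- .shared_kmers(K, K[, qs, drop = FALSE])  # n x |qs|
      for (t in seq_along(qs)) {
        q <- qs[t]
        # reference neighbours: strictly more abundant than the query (a
        # parent must out-number its chimera); independent of abskew
        ref <- which(ab > ab[q])
        if (length(ref) == 0) next
        ref_sets[[q]] <- topk(ref, shared[ref, t])
        mod <- which(ab >= params$abskew * ab[q] & ab > ab[q])
        if (length(mod)) mod_sets[[q]] <- topk(mod, shared[mod, t])
      }
    }
    # batch alignments grouped by candidate (and orientation)
    pairs <- tibble(
      q = c(rep(seq_len(n), lengths(ref_sets)), rep(seq_len(n), lengths(mod_sets))),
      c = c(unlist(ref_sets) %||% integer(0), unlist(mod_sets) %||% integer(0))
    )
    pairs <- pairs[!duplicated(pairs), , drop = FALSE]
    mv <- new.env(parent = emptyenv())
    if (nrow(pairs)) {
      for (ci in unique(pairs$c)) {
        qs <- pairs$q[pairs$c == ci]
        res <- .global_match_vectors(records$seq[qs], records$seq[ci], scoring)
        for (t in seq_along(qs)) {
          assign(paste0(qs[t], "_", ci, "_f"), res[[t]], envir = mv)
        }
        if (params$both_strands) {
          qs_m <- qs[qs %in% which(lengths(mod_sets) > 0)]
          qs_m <- qs_m[vapply(qs_m, function(z) ci %in% mod_sets[[z]], logical(1))]
          for (qm in qs_m) {
            assign(paste0(qm, "_", ci, "_r"),
                   .rc_match_vector(records$seq[qm], records$seq[ci], scoring),
                   envir = mv)
          }
        }
      }
    }
    for (q in seq_len(n)) {
      rs <- ref_sets[[q]]
      if (is.null(rs) || length(rs) == 0) next
      ref_mv <- lapply(paste0(q, "_", rs, "_f"), get, envir = mv)
      ref_best <- max(vapply(ref_mv, function(x) sum(x$match), numeric(1)))
      ref_div <- 100 - max(vapply(ref_mv, `[[`, numeric(1), "identity_pct"))
      cs <- mod_sets[[q]]
      mvecs <- list(); ids <- character(0)
      if (!is.null(cs) && length(cs) > 0) {
        mvecs <- lapply(paste0(q, "_", cs, "_f"), get, envir = mv)
        ids <- records$id[cs]
        if (params$both_strands) {
          mvecs <- c(mvecs, lapply(paste0(q, "_", cs, "_r"), get, envir = mv))
          ids <- c(ids, records$id[cs])
        }
      }
      evidence[[q]] <- .evaluate_query(mvecs, ids, ref_best, ref_div, params)
    }
  }
  .calls_tibble(records$id, evidence, params)
}

.calls_tibble <- function(query_ids, evidence, params) {
  get1 <- function(field, proto) {
    vapply(evidence, function(e) e[[field]] %||% proto, proto)
  }
  out <- tibble(
    query_id = query_ids,
    has_model = if (length(evidence)) get1("has_model", NA) else logical(0),
    parents = purrr::map(evidence, "parents"),
    breakpoints = purrr::map(evidence, "breakpoints"),
    y_total = if (length(evidence)) as.integer(get1("y_total", NA_integer_)) else integer(0),
    n_total = if (length(evidence)) as.integer(get1("n_total", NA_integer_)) else integer(0),
    a_total = if (length(evidence)) as.integer(get1("a_total", NA_integer_)) else integer(0),
    y_min = if (length(evidence)) as.integer(get1("y_min", NA_integer_)) else integer(0),
    div_pct = if (length(evidence)) get1("div_pct", NA_real_) else numeric(0),
    model_diff_pct = if (length(evidence)) get1("model_diff_pct", NA_real_) else numeric(0),
    model_gain_pp = if (length(evidence)) get1("model_gain_pp", NA_real_) else numeric(0),
    seg_ident_min = if (length(evidence)) get1("seg_ident_min", NA_real_) else numeric(0),
    model_score = if (length(evidence)) get1("model_score", NA_real_) else numeric(0),
    best_single_score = if (length(evidence)) get1("best_single_score", NA_real_) else numeric(0)
  )
  out <- rescore_calls(out, params)
  out
}

#' Re-apply verdict thresholds to existing detector evidence
#'
#' The best chimeric model of a query depends only on the structural
#' parameters (`abskew`, `parts`, `min_segment_len`, `top_candidates`,
#' `kmer`, `both_strands`); the verdict thresholds (`minh`, `mindiffs`,
#' `dn`, `xn`, `mindiv`, `max_diff_pct`) only re-weight and gate the stored
#' votes. This function recomputes `h` and `verdict` from a calls table
#' under new thresholds without re-aligning — exactly equivalent to a full
#' [detect_chimeras()] run that differs only in threshold parameters.
#'
#' @param calls A calls tibble from [detect_chimeras()].
#' @param params A [detector_params()].
#' @return The calls tibble with `h` and `verdict` recomputed.
#' @export
rescore_calls <- function(calls, params) {
  old <- attr(calls, "params")
  if (!is.null(old)) {
    structural <- c("abskew", "parts", "min_segment_len", "top_candidates",
                    "kmer", "both_strands")
    for (f in structural) {
      if (!identical(old[[f]], params[[f]])) {
        abort(paste0("rescore_calls: structural parameter '", f,
                     "' differs; rerun detect_chimeras"))
      }
    }
  }
  v <- .call_verdict(calls$has_model, calls$y_total, calls$n_total,
                     calls$a_total, calls$y_min, calls$div_pct,
                     calls$model_diff_pct, calls$model_gain_pp,
                     calls$seg_ident_min, params)
  calls$h <- v$h
  calls$verdict <- v$verdict
  calls <- calls[, unique(c("query_id", "verdict", "h",
                            setdiff(names(calls), c("query_id", "verdict", "h"))))]
  attr(calls, "params") <- params
  calls
}

#' Brute-force reference detector for small instances
#'
#' Identical contract to [detect_chimeras()] but with no kmer pruning (every
#' abundance-eligible candidate is considered) and a direct exhaustive scan
#' over breakpoints with per-segment vote recounts. Serves as the
#' equivalence oracle for the vectorized engine. Refuses instances larger
#' than 50 records or 1,000 bp.
#'
#' @inheritParams detect_chimeras
#' @return A calls tibble as in [detect_chimeras()].
#' @export
detect_bruteforce <- function(records, params = detector_params(),
                              scoring = align_scoring()) {
  validate_amplicons(records)
  if (nrow(records) > 50 || any(nchar(records$seq) > 1000)) {
    abort("detect_bruteforce: instance too large (max 50 records of 1,000 bp)")
  }
  records <- records |> arrange(desc(abundance), id)
  n <- nrow(records)
  empty_ev <- list(has_model = FALSE, parents = character(0),
                   breakpoints = integer(0), y_total = NA_integer_,
                   n_total = NA_integer_, a_total = NA_integer_,
                   y_min = NA_integer_, div_pct = NA_real_,
                   model_diff_pct = NA_real_, model_gain_pp = NA_real_,
                   seg_ident_min = NA_real_,
                   model_score = NA_real_, best_single_score = NA_real_)
  evidence <- rep(list(empty_ev), n)
  for (q in seq_len(n)) {
    ab_q <- records$abundance[q]
    ref <- which(records$abundance > ab_q)
    if (length(ref) == 0) next
    ref_aln <- lapply(ref, function(ci)
      align_global(records$seq[q], records$seq[ci], scoring))
    ref_best <- max(vapply(ref_aln, function(g) sum(g$match), numeric(1)))
    ref_div <- 100 - max(vapply(ref_aln, `[[`, numeric(1), "identity_pct"))
    cs <- ref[records$abundance[ref] >= params$abskew * ab_q]
    mvecs <- list(); ids <- character(0)
    for (ci in cs) {
      g <- ref_aln[[match(ci, ref)]]
      mvecs[[length(mvecs) + 1]] <- list(match = g$match,
                                         identity_pct = g$identity_pct)
      ids <- c(ids, records$id[ci])
      if (params$both_strands) {
        mvecs[[length(mvecs) + 1]] <- .rc_match_vector(records$seq[q],
                                                       records$seq[ci], scoring)
        ids <- c(ids, records$id[ci])
      }
    }
    evidence[[q]] <- .bruteforce_models(mvecs, ids, ref_best, ref_div, params)
  }
  .calls_tibble(records$id, evidence, params)
}

# exhaustive model scan: direct sums per breakpoint, no prefix tricks beyond
# what an enumeration needs
.bruteforce_models <- function(mvecs, ids, ref_best_matches, ref_div_pct, params) {
  ev <- list(has_model = FALSE, parents = character(0), breakpoints = integer(0),
             y_total = NA_integer_, n_total = NA_integer_, a_total = NA_integer_,
             y_min = NA_integer_, div_pct = ref_div_pct,
             model_diff_pct = NA_real_, model_gain_pp = NA_real_,
             seg_ident_min = NA_real_,
             model_score = NA_real_, best_single_score = ref_best_matches)
  if (length(mvecs) == 0) return(ev)
  m <- lapply(mvecs, `[[`, "match")
  L <- length(m[[1]])
  minseg <- params$min_segment_len
  S <- vapply(m, sum, numeric(1))
  if (L < 2L * minseg) return(ev)
  ord <- order(ids)
  best_score <- -Inf; tied <- list()
  push <- function(score, parents, bounds) {
    if (score > best_score) { best_score <<- score; tied <<- list() }
    if (score == best_score) {
      tied[[length(tied) + 1]] <<- list(parents = parents, bounds = bounds)
    }
  }
  # each ordered pair contributes its best model at the smallest breakpoint
  for (i in ord) for (j in ord) {
    if (ids[i] == ids[j]) next
    ps <- -Inf; pb <- NA_integer_
    for (b in minseg:(L - minseg)) {
      sc <- sum(m[[i]][1:b]) + sum(m[[j]][(b + 1):L])
      if (sc > ps) { ps <- sc; pb <- b }
    }
    push(ps, c(i, j), c(pb, L))
  }
  if (params$parts == 3L && L >= 3L * minseg && length(unique(ids)) >= 2) {
    for (i in ord) for (j in ord) {
      if (ids[i] == ids[j]) next
      for (k in ord) {
        if (ids[k] == ids[j]) next
        ps <- -Inf; pbounds <- NULL
        for (b2 in (2L * minseg):(L - minseg)) {
          for (b1 in minseg:(b2 - minseg)) {
            sc <- sum(m[[i]][1:b1]) + sum(m[[j]][(b1 + 1):b2]) +
              sum(m[[k]][(b2 + 1):L])
            if (sc > ps) { ps <- sc; pbounds <- c(b1, b2, L) }
          }
        }
        push(ps, c(i, j, k), pbounds)
      }
    }
  }
  if (best_score <= ev$best_single_score) return(ev)
  best <- NULL
  for (cand in tied) {
    v <- .model_votes(m, cand$parents, cand$bounds)
    entry <- list(score = best_score, y_total = sum(v$y),
                  key = paste(ids[cand$parents], collapse = "\r"),
                  parents = cand$parents, bounds = cand$bounds, votes = v)
    if (.better_model(entry, best)) best <- entry
  }
  ev$has_model <- TRUE
  ev$parents <- ids[best$parents]
  ev$breakpoints <- head(best$bounds, -1)
  ev$y_total <- sum(best$votes$y); ev$n_total <- sum(best$votes$n)
  ev$a_total <- sum(best$votes$a); ev$y_min <- min(best$votes$y)
  ev$seg_ident_min <- min(best$votes$seg_ident)
  ev$model_score <- best_score
  ev$model_diff_pct <- 100 * (L - best_score) / L
  ev$model_gain_pp <- 100 * (best_score - ev$best_single_score) / L
  ev
}
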