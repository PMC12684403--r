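#' Score detector calls against truth labels
#'
#' The positive truth class is any planted artifact (`pcr_chimera` and, by
#' default, `concatemer`); the predicted positive class is verdict `chimera`
#' plus, by default, `borderline` (borderline calls are counted as chimeras
#' when benchmarking). Per-class recalls for PCR chimeras and concatemers
#' are reported alongside.
#'
#' Degenerate conventions (stated because the formulas are undefined there):
#' with no true positives possible (`tp + fn == 0`) and no false positives,
#' precision, recall and F1 are all 1; otherwise `tp + fp == 0` gives
#' precision 0, and F1 is 0 whenever precision + recall is 0.
#'
#' @param calls Calls tibble from [detect_chimeras()] (or any tibble with
#'   `query_id` and `verdict`).
#' @param truth Truth tibble (`read_id`, `klass`); every call id must be
#'   present.
#' @param borderline_as_chimera Count `borderline` verdicts as chimeric?
#' @param include_concatemers Count concatemers in the positive truth class?
#' @return A one-row tibble of class `chim_confusion`: `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`, `recall_pcr`, `recall_concatemer`,
#'   `n`.
#' @examples
#' calls <- tibble::tibble(query_id = c("a", "b"),
#'                         verdict = c("chimera", "clean"))
#' truth <- tibble::tibble(read_id = c("a", "b"),
#'                         klass = c("pcr_chimera", "parental"))
#' score_calls(calls, truth)
#' @export
score_calls <- function(calls, truth, borderline_as_chimera = TRUE,
                        include_concatemers = TRUE) {
  at <- match(calls$query_id, truth$read_id)
  if (anyNA(at)) {
    abort(paste0("score_calls: no truth row for call id ",
                 calls$query_id[which(is.na(at))[1]]))
  }
  klass <- truth$klass[at]
  pos_classes <- if (include_concatemers) c("pcr_chimera", "concatemer") else
    "pcr_chimera"
  is_pos <- klass %in% pos_classes
  pred <- calls$verdict == "chimera"
  if (borderline_as_chimera) pred <- pred | calls$verdict == "borderline"
  if (!include_concatemers) {
    keep <- klass != "concatemer"
    is_pos <- is_pos[keep]; pred <- pred[keep]; klass <- klass[keep]
  }
  tp <- sum(pred & is_pos); fp <- sum(pred & !is_pos)
  fn <- sum(!pred & is_pos); tn <- sum(!pred & !is_pos)
  if (tp + fn == 0 && fp == 0) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 1
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  class_recall <- function(cl) {
    in_cl <- klass == cl
    if (!any(in_cl)) return(NA_real_)
    sum(pred & in_cl) / sum(in_cl)
  }
  out <- tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1,
    recall_pcr = class_recall("pcr_chimera"),
    recall_concatemer = class_recall("concatemer"),
    n = length(pred)
  )
  class(out) <- c("chim_confusion", class(out))
  out
}

#' Confusion metrics from printed counts
#'
#' Builds a minimal calls-plus-truth dataset realizing the given counts and
#' scores it with [score_calls()] — the worked-example route from a
#' publication's printed TP/FP/true-chimera numbers to precision, recall and
#' F1 under this package's scoring.
#'
#' @param tp True positives (detected true chimeras).
#' @param fp False positives (non-chimeras flagged).
#' @param n_true Total true chimeras in the dataset.
#' @param n_total Total reads (defaults to a minimal dataset).
#' @return A `chim_confusion` one-row tibble.
#' @examples
#' confusion_from_counts(1991, 2, 2484)$f1 # about 0.889
#' @export
confusion_from_counts <- function(tp, fp, n_true, n_total = NULL) {
  stopifnot(tp <= n_true, fp >= 0)
  n_total <- n_total %||% (n_true + fp + 1L)
  n_neg <- n_total - n_true
  stopifnot(fp <= n_neg)
  truth <- tibble(
    read_id = c(sprintf("chim%06d", seq_len(n_true)),
                sprintf("par%06d", seq_len(n_neg))),
    klass = c(rep("pcr_chimera", n_true), rep("parental", n_neg))
  )
  calls <- tibble(
    query_id = truth$read_id,
    verdict = c(rep("chimera", tp), rep("clean", n_true - tp),
                rep("chimera", fp), rep("clean", n_neg - fp))
  )
  score_calls(calls, truth)
}

#' Sweep detector parameters over a grid
#'
#' Runs [detect_chimeras()] and [score_calls()] at every row of a parameter
#' grid. Rows are evaluated in grid order; grid columns may name any
#' [detector_params()] field, unnamed fields keep their defaults. Rows that
#' differ only in threshold parameters share one alignment pass via
#' [rescore_calls()].
#'
#' @param records Dereplicated amplicon table.
#' @param grid A tibble, one row per parameter combination.
#' @param truth Truth tibble covering every record id.
#' @param base_params Defaults for fields absent from the grid.
#' @param borderline_as_chimera,include_concatemers Passed to [score_calls()].
#' @return A `chim_sweep` tibble: the grid columns plus `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`.
#' @export
run_sweep <- function(records, grid, truth, base_params = detector_params(),
                      borderline_as_chimera = TRUE, include_concatemers = TRUE) {
  if (nrow(grid) == 0) abort("run_sweep: empty grid")
  bad <- setdiff(names(grid), names(base_params))
  if (length(bad)) {
    abort(paste0("run_sweep: unknown detector parameter: ", bad[1]))
  }
  params_for <- function(i) {
    p <- unclass(base_params)
    for (f in names(grid)) {
      v <- grid[[f]][i]
      if (!is.na(v)) p[[f]] <- v   # NA grid cells keep the default
    }
    do.call(detector_params, p)
  }
  structural <- c("abskew", "parts", "min_segment_len", "top_candidates",
                  "kmer", "both_strands")
  key_of <- function(p) paste(vapply(structural, function(f)
    format(p[[f]]), character(1)), collapse = "|")
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params_for(i)
    key <- key_of(p)
    if (!exists(key, envir = cache)) {
      assign(key, detect_chimeras(records, p), envir = cache)
    }
    calls <- rescore_calls(get(key, envir = cache), p)
    counts <- score_calls(calls, truth, borderline_as_chimera,
                          include_concatemers)
    rows[[i]] <- dplyr::bind_cols(
      grid[i, , drop = FALSE],
      counts[, c("tp", "fp", "fn", "tn", "precision", "recall", "f1")]
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("chim_sweep", class(out))
  attr(out, "base_params") <- base_params
  out
}

#' Pick the best sweep row
#'
#' Argmax F1; ties go to higher precision, then to the row changing fewer
#' parameters away from the detector defaults, then to grid order.
#'
#' @param rows A `chim_sweep` tibble (or any tibble with the metric columns).
#' @param base_params Defaults used for the fewest-changes tie-break.
#' @return The selected one-row tibble.
#' @export
select_best <- function(rows, base_params = detector_params()) {
  if (nrow(rows) == 0) abort("select_best: no rows")
  param_cols <- intersect(names(rows), names(base_params))
  n_changed <- vapply(seq_len(nrow(rows)), function(i) {
    sum(vapply(param_cols, function(f)
      !isTRUE(all.equal(rows[[f]][i], base_params[[f]])), logical(1)))
  }, numeric(1))
  ord <- order(-rows$f1, -rows$precision, n_changed, seq_len(nrow(rows)))
  rows[ord[1], , drop = FALSE]
}

#' Preset parameter grids
#'
#' One-factor-at-a-time grids over the classic tested ranges of the two
#' detector families, plus combination runs around the best-performing
#' settings: 49 rows for the uchime-style family (dn 1.4-2.0, mindiffs 2-4,
#' minh 0.28 down to 0.05, abskew 2-16, xn 2-3, mindiv 0.4/0.6, plus
#' abskew 3 crossed with the low minh values) and 22 rows for the long-read
#' family (diff_pct 0.5-0.9, segment length 10-60, parts 2-3, abskew 2-6,
#' plus abskew 4 / length 30 / diff_pct 0.6-0.9 combinations).
#'
#' @return A tibble usable as the `grid` of [run_sweep()].
#' @export
sweep_grid_uchime <- function() {
  bind_rows(
    tibble(minh = 0.28),                                   # defaults row
    tibble(dn = c(1.6, 1.8, 2.0)),
    tibble(mindiffs = c(2L, 4L)),
    tibble(minh = c(seq(0.26, 0.10, by = -0.02), seq(0.09, 0.05, by = -0.01))),
    tibble(abskew = 3:16),
    tibble(xn = 3),
    tibble(mindiv = c(0.4, 0.6)),
    tibble(abskew = 3, minh = c(seq(0.05, 0.09, by = 0.01),
                                seq(0.10, 0.22, by = 0.02)))
  )
}

#' @rdname sweep_grid_uchime
#' @export
sweep_grid_chimeras_denovo <- function() {
  bind_rows(
    tibble(abskew = 1),                                    # family defaults
    tibble(abskew = 1, max_diff_pct = c(0.5, 0.6, 0.7, 0.8, 0.9)),
    tibble(abskew = 1, min_segment_len = c(20L, 30L, 40L, 50L, 60L)),
    tibble(abskew = 1, parts = c(2L, 3L)),
    tibble(abskew = 2:6),
    tibble(abskew = 4, min_segment_len = 30L,
           max_diff_pct = c(0.6, 0.7, 0.8, 0.9))
  )
}
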