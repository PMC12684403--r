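test_that("score_calls equals a direct confusion recount", {
  set.seed(71)
  n <- 200
  truth <- tibble::tibble(
    read_id = sprintf("r%03d", 1:n),
    klass = sample(c("parental", "pcr_chimera", "concatemer"), n,
                   replace = TRUE, prob = c(0.8, 0.15, 0.05))
  )
  calls <- tibble::tibble(
    query_id = truth$read_id,
    verdict = sample(c("chimera", "borderline", "clean"), n,
                     replace = TRUE, prob = c(0.15, 0.05, 0.8))
  )
  sc <- score_calls(calls, truth)
  pred <- calls$verdict != "clean"
  pos <- truth$klass != "parental"
  expect_equal(sc$tp, sum(pred & pos))
  expect_equal(sc$fp, sum(pred & !pos))
  expect_equal(sc$fn, sum(!pred & pos))
  expect_equal(sc$tn, sum(!pred & !pos))
  expect_equal(sc$tp + sc$fp + sc$fn + sc$tn, n)
  expect_equal(sc$precision, sc$tp / (sc$tp + sc$fp))
  expect_equal(sc$recall, sc$tp / (sc$tp + sc$fn))
  expect_equal(sc$f1, 2 * sc$precision * sc$recall / (sc$precision + sc$recall))
  # f1 never exceeds twice the weaker side
  expect_lte(sc$f1, 2 * min(sc$precision, sc$recall))
  # borderline counted as clean when the flag is off
  sc2 <- score_calls(calls, truth, borderline_as_chimera = FALSE)
  pred2 <- calls$verdict == "chimera"
  expect_equal(sc2$tp, sum(pred2 & pos))
  # concatemers can be excluded from scoring
  sc3 <- score_calls(calls, truth, include_concatemers = FALSE)
  keep <- truth$klass != "concatemer"
  expect_equal(sc3$n, sum(keep))
  expect_error(score_calls(tibble::tibble(query_id = "zz", verdict = "clean"),
                           truth), "no truth row")
})

test_that("degenerate scoring conventions hold", {
  truth <- tibble::tibble(read_id = c("a", "b"), klass = rep("parental", 2))
  calls <- tibble::tibble(query_id = c("a", "b"), verdict = rep("clean", 2))
  sc <- score_calls(calls, truth)
  expect_equal(c(sc$precision, sc$recall, sc$f1), c(1, 1, 1))
  # false alarms with no true chimeras: precision 0
  calls$verdict <- c("chimera", "clean")
  sc2 <- score_calls(calls, truth)
  expect_equal(sc2$precision, 0)
  expect_equal(sc2$f1, 0)
})

test_that("per-class recall separates PCR chimeras from concatemers", {
  truth <- tibble::tibble(
    read_id = c("c1", "c2", "k1", "p1"),
    klass = c("pcr_chimera", "pcr_chimera", "concatemer", "parental")
  )
  calls <- tibble::tibble(query_id = truth$read_id,
                          verdict = c("chimera", "clean", "chimera", "clean"))
  sc <- score_calls(calls, truth)
  expect_equal(sc$recall_pcr, 0.5)
  expect_equal(sc$recall_concatemer, 1)
})

test_that("a single-point sweep equals direct detect + score", {
  set.seed(72)
  recs <- small_instance(n_templates = 3, len = 90)
  truth <- tibble::tibble(
    read_id = recs$id,
    klass = ifelse(recs$id == "chimX", "pcr_chimera", "parental")
  )
  p <- detector_params(min_segment_len = 5L)
  grid <- tibble::tibble(minh = 0.28)
  sw <- run_sweep(recs, grid, truth, base_params = p)
  direct <- score_calls(detect_chimeras(recs, p), truth)
  expect_equal(sw$tp, direct$tp)
  expect_equal(sw$f1, direct$f1)
  expect_error(run_sweep(recs, tibble::tibble(bogus = 1), truth), "unknown")
})

test_that("sweeping minh and abskew moves recall in the documented direction", {
  d <- bench_dataset()
  truth <- d$truth
  grid <- tibble::tibble(minh = c(0.28, 0.10))
  sw <- run_sweep(d$derep, grid, truth)
  expect_gte(sw$recall[sw$minh == 0.10], sw$recall[sw$minh == 0.28])
})

test_that("select_best maximizes F1 with precision and parsimony tie-breaks", {
  rows <- tibble::tibble(minh = c(0.28, 0.2, 0.1),
                         precision = c(0.9, 0.8, 0.95),
                         recall = c(0.5, 0.9, 0.7),
                         f1 = c(0.5, 0.9, 0.7))
  expect_equal(select_best(rows)$f1, 0.9)
  ties <- tibble::tibble(minh = c(0.28, 0.2), precision = c(0.8, 0.95),
                         recall = c(0.7, 0.7), f1 = c(0.7, 0.7))
  expect_equal(select_best(ties)$precision, 0.95)
  # equal f1 and precision: prefer the row closer to the defaults
  ties2 <- tibble::tibble(minh = c(0.2, 0.28), precision = c(0.9, 0.9),
                          recall = c(0.7, 0.7), f1 = c(0.7, 0.7))
  expect_equal(select_best(ties2)$minh, 0.28)
  # random rows equal an exhaustive scan on f1
  set.seed(73)
  rnd <- tibble::tibble(minh = runif(20, 0.05, 0.3), precision = runif(20),
                        recall = runif(20), f1 = runif(20))
  expect_equal(select_best(rnd)$f1, max(rnd$f1))
})

test_that("preset grids mirror the published run-count structure", {
  gu <- sweep_grid_uchime()
  expect_equal(nrow(gu), 49)
  expect_true(any(!is.na(gu$abskew) & gu$abskew == 3 &
                  !is.na(gu$minh) & gu$minh == 0.09))
  gc <- sweep_grid_chimeras_denovo()
  expect_equal(nrow(gc), 22)
  expect_true(any(gc$abskew == 4 & !is.na(gc$min_segment_len) &
                  gc$min_segment_len == 30 & !is.na(gc$max_diff_pct) &
                  gc$max_diff_pct == 0.9))
})

test_that("tidy and glance methods expose confusion and sweep results", {
  sc <- confusion_from_counts(10, 2, 20)
  td <- generics::tidy(sc)
  expect_equal(td$value[td$metric == "tp"], 10)
  expect_s3_class(generics::glance(sc), "tbl_df")
  rows <- tibble::tibble(minh = c(0.28, 0.1), precision = c(1, 0.9),
                         recall = c(0.5, 0.9), f1 = c(2/3, 0.9))
  class(rows) <- c("chim_sweep", class(rows))
  expect_equal(generics::glance(rows)$f1, 0.9)
  pl <- autoplot(rows)
  expect_s3_class(pl, "ggplot")
})
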