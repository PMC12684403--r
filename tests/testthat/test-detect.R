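test_that("a clean two-parent chimera is detected with h = 1", {
  set.seed(61)
  a <- rnd_dna(400); b <- rnd_dna(400)
  recs <- amplicon_tbl(
    c("A", "B", "Q"),
    c(a, b, paste0(substr(a, 1, 200), substr(b, 201, 400))),
    abundance = c(10L, 10L, 1L)
  )
  calls <- detect_chimeras(recs, detector_params())
  q <- calls[calls$query_id == "Q", ]
  expect_equal(q$verdict, "chimera")
  expect_equal(q$h, 1)
  expect_setequal(q$parents[[1]], c("A", "B"))
  # h = 1 exactly when the model explains every informative column
  expect_equal(q$n_total, 0L)
  expect_equal(q$a_total, 0L)
  expect_gt(q$y_total, 0)
})

test_that("a query identical to a parent is clean", {
  set.seed(62)
  a <- rnd_dna(300); b <- rnd_dna(300)
  recs <- amplicon_tbl(c("A", "B", "Q"), c(a, b, a), abundance = c(10L, 10L, 1L))
  expect_warning(calls <- detect_chimeras(recs, detector_params()), "duplicate")
  expect_equal(calls$verdict[calls$query_id == "Q"], "clean")
  expect_equal(calls$div_pct[calls$query_id == "Q"], 0)
})

test_that("equal abundances leave no testable query", {
  set.seed(63)
  recs <- amplicon_tbl(c("A", "B", "C"), replicate(3, rnd_dna(200)),
                       abundance = c(5L, 5L, 5L))
  calls <- detect_chimeras(recs, detector_params(abskew = 16))
  expect_true(all(calls$verdict == "clean"))
  expect_true(all(!calls$has_model))
})

test_that("reverse-complement-segment chimeras evade the default strand mode", {
  set.seed(64)
  a <- rnd_dna(400); b <- rnd_dna(400)
  q <- paste0(substr(a, 1, 200), revcomp(substr(b, 201, 400)))
  recs <- amplicon_tbl(c("A", "B", "Q"), c(a, b, q), abundance = c(10L, 10L, 1L))
  fwd <- detect_chimeras(recs, detector_params())
  expect_equal(fwd$verdict[fwd$query_id == "Q"], "clean")
  both <- detect_chimeras(recs, detector_params(both_strands = TRUE))
  expect_equal(both$verdict[both$query_id == "Q"], "chimera")
})

test_that("h stays in [0,1] and verdicts carry parents", {
  set.seed(65)
  for (i in 1:10) {
    recs <- small_instance()
    calls <- detect_chimeras(recs, detector_params(min_segment_len = 5L))
    expect_true(all(calls$h >= 0 & calls$h <= 1))
    called <- calls$verdict %in% c("chimera", "borderline")
    expect_true(all(lengths(calls$parents[called]) >= 2))
    perfect <- !is.na(calls$y_total) & calls$n_total == 0 &
      calls$a_total == 0 & calls$y_total > 0
    expect_true(all(calls$h[perfect] == 1))
  }
})

test_that("rescoring thresholds equals a fresh run for threshold params", {
  set.seed(66)
  recs <- small_instance(n_templates = 3, len = 100)
  base <- detect_chimeras(recs, detector_params(min_segment_len = 5L))
  for (p in list(detector_params(minh = 0.1, min_segment_len = 5L),
                 detector_params(dn = 2, xn = 3, min_segment_len = 5L),
                 detector_params(mindiv = 0.4, mindiffs = 2L, min_segment_len = 5L),
                 detector_params(max_diff_pct = 5, min_segment_len = 5L))) {
    full <- detect_chimeras(recs, p)
    fast <- rescore_calls(base, p)
    expect_equal(fast$verdict, full$verdict)
    expect_equal(fast$h, full$h)
  }
  expect_error(rescore_calls(base, detector_params(abskew = 4)), "structural")
})

test_that("the brute-force oracle rejects oversized instances", {
  recs <- amplicon_tbl(sprintf("r%02d", 1:51), replicate(51, rnd_dna(20)))
  expect_error(detect_bruteforce(recs), "too large")
  expect_error(detect_bruteforce(amplicon_tbl("a", rnd_dna(1200))), "too large")
})

test_that("degenerate inputs yield empty or clean calls", {
  empty <- detect_chimeras(amplicon_tbl(character(0), character(0))[0, ],
                           detector_params())
  expect_equal(nrow(empty), 0)
  one <- detect_chimeras(amplicon_tbl("a", rnd_dna(100)), detector_params())
  expect_equal(one$verdict, "clean")
  b1 <- detect_bruteforce(amplicon_tbl("a", rnd_dna(100)), detector_params())
  expect_equal(b1$verdict, "clean")
})
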