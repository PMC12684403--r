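test_that("global alignment matches an independent DP oracle on small pairs", {
  expect_equal(align_global("ACGT", "ACGT")$identity_pct, 100)
  expect_equal(align_global("ACGT", "ACCT")$identity_pct, 75)
  set.seed(31)
  for (i in 1:40) {
    a <- rnd_dna(sample(3:30, 1)); b <- rnd_dna(sample(3:30, 1))
    g <- align_global(a, b)
    expect_equal(g$score, nw_score_oracle(a, b), info = paste(a, b))
    # column map strips back to the inputs
    expect_equal(gsub("-", "", g$aligned_a), a)
    expect_equal(gsub("-", "", g$aligned_b), b)
  }
  expect_error(align_global("", "ACGT"), "empty")
})

test_that("semi-global identity tracks planted mutations; coverage is 100", {
  set.seed(32)
  t1 <- rnd_dna(600)
  q0 <- substr(t1, 101, 300)
  sg <- align_semiglobal(q0, t1)
  expect_equal(sg$identity_pct, 100)
  expect_equal(sg$coverage_pct, 100)
  for (i in 1:10) {
    k <- sample(1:8, 1)
    q <- mutate_seq(q0, k)
    sg <- align_semiglobal(q, t1)
    expect_lt(abs(sg$identity_pct - (1 - k / 200) * 100), 0.5)
  }
})

test_that("find_hsps splits a two-block chimera and masks query intervals", {
  set.seed(33)
  target <- rnd_dna(900)
  # query = two disjoint 300 bp blocks of the target, separated in the target
  query <- paste0(substr(target, 1, 300), substr(target, 601, 900))
  hit <- find_hsps(query, target)
  expect_equal(hit$n_hsps, 2)
  expect_true(all(abs(hit$hsps$query_coverage_pct - 50) < 2))
  # intervals must not overlap
  hs <- hit$hsps[order(hit$hsps$q_start), ]
  expect_true(all(hs$q_end[-nrow(hs)] < hs$q_start[-1]))
  # identical query: one full-coverage HSP
  hit1 <- find_hsps(target, target)
  expect_equal(hit1$n_hsps, 1)
  expect_equal(hit1$query_coverage_pct, 100)
  # unrelated sequences: no hit above the score floor
  hit0 <- find_hsps(rnd_dna(60), rnd_dna(60))
  expect_equal(hit0$n_hsps, 0)
})

test_that("find_hsps reports reverse-strand segments", {
  set.seed(34)
  target <- rnd_dna(500)
  query <- paste0(substr(target, 1, 200), revcomp(substr(target, 301, 500)))
  hit <- find_hsps(query, target, both_strands = TRUE)
  expect_setequal(hit$hsps$strand, c("+", "-"))
  fwd_only <- find_hsps(query, target, both_strands = FALSE)
  expect_true(all(fwd_only$hsps$strand == "+"))
})

test_that("best_hit equals an exhaustive scan and honors self-exclusion", {
  set.seed(35)
  base <- rnd_dna(200)
  db <- amplicon_tbl(sprintf("d%02d", 1:20),
                     c(base, replicate(19, rnd_dna(200))))
  query <- amplicon_tbl("q", mutate_seq(base, 3))
  hit <- best_hit(query, db, mode = "semiglobal", prescreen = 0)
  # exhaustive oracle
  scores <- vapply(db$seq, function(t) align_semiglobal(query$seq, t)$score,
                   numeric(1))
  expect_equal(hit$target_id, db$id[which.max(scores)])
  # prescreen finds the same best hit here
  hit2 <- best_hit(query, db, mode = "semiglobal", prescreen = 5)
  expect_equal(hit2$target_id, hit$target_id)
  # self-exclusion
  db2 <- amplicon_tbl(c("q", "m"), c(query$seq, mutate_seq(query$seq, 2)))
  h_excl <- best_hit(query, db2, mode = "semiglobal", exclude_self = TRUE)
  expect_equal(h_excl$target_id, "m")
  h_self <- best_hit(query, db2, mode = "semiglobal", exclude_self = FALSE)
  expect_equal(h_self$target_id, "q")
  expect_equal(h_self$best_identity_pct, 100)
  expect_null(best_hit(query, db2[db2$id == "q", ], exclude_self = TRUE))
})

test_that("hits export as BLAST outfmt-6-like rows", {
  set.seed(36)
  t1 <- rnd_dna(400)
  h <- find_hsps(paste0(substr(t1, 1, 150), substr(t1, 251, 400)), t1,
                 query_id = "q1", target_id = "t1")
  tab <- hits_to_blast6(list(h))
  expect_equal(names(tab), c("qseqid", "sseqid", "pident", "length", "qstart",
                             "qend", "sstart", "send", "score", "qcovhsp"))
  expect_equal(nrow(tab), h$n_hsps)
  expect_true(all(tab$qseqid == "q1"))
})
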