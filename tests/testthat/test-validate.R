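test_that("rescue honors the inclusive 99% identity boundary", {
  set.seed(81)
  ref <- amplicon_tbl("ref1", rnd_dna(300))
  exact <- amplicon_tbl("q0", ref$seq)
  at99 <- amplicon_tbl("q3", mutate_seq(ref$seq, 3))    # 297/300 = 99.0%
  below <- amplicon_tbl("q4", mutate_seq(ref$seq, 4))   # 296/300 = 98.7%
  out <- rescue_false_positives(dplyr::bind_rows(exact, at99, below), ref)
  expect_equal(out$verdict, c("fp_rescued", "fp_rescued", "true_chimera"))
  expect_equal(out$identity_pct[1], 100)
  expect_equal(out$identity_pct[2], 99)
})

test_that("chimeras of divergent parents are never rescued", {
  d <- bench_dataset()
  chims <- balanced_chimeras(d, 25)
  out <- rescue_false_positives(chims, d$templates[, c("id", "seq")])
  expect_true(all(out$verdict == "true_chimera"))
})

test_that("the first-HSP coverage rule is strict at 85%", {
  set.seed(83)
  q <- rnd_dna(200)
  # target A: exact copy of query[1:170] (85.0% coverage) + the tail elsewhere
  make_target <- function(cut) {
    paste0(substr(q, 1, cut), rnd_dna(120), substr(q, cut + 1, 200))
  }
  db_at <- amplicon_tbl("t85", make_target(170L))
  db_below <- amplicon_tbl("t84", make_target(169L))
  query <- amplicon_tbl("q", q)
  at <- flag_false_negatives(query, db_at[0, ], db_at)
  expect_equal(at$n_hsps, 2L)
  expect_equal(at$first_hsp_cov_pct, 85)
  expect_equal(at$verdict, "non_chimera")      # rule requires < 85
  below <- flag_false_negatives(query, db_below[0, ], db_below)
  expect_equal(below$first_hsp_cov_pct, 84.5)
  expect_equal(below$verdict, "fn_chimera")
})

test_that("parental reads are not flagged; verdicts ignore input order", {
  d <- bench_dataset()
  set.seed(84)
  pars <- d$records[d$records$truth_class == "parental", ][1:15, c("id", "seq")]
  out <- flag_false_negatives(pars, d$derep[, c("id", "seq")],
                              d$templates[, c("id", "seq")])
  expect_true(all(out$verdict == "non_chimera"))
  shuffled <- flag_false_negatives(pars[15:1, ], d$derep[, c("id", "seq")],
                                   d$templates[, c("id", "seq")])
  expect_equal(out[order(out$read_id), ], shuffled[order(shuffled$read_id), ])
})

test_that("count_58s is exact on planted structures and silent on noise", {
  d <- bench_dataset()
  vc <- validation_config(r58s_model = d$consensus)
  pars <- d$records[d$records$truth_class == "parental", ][1:10, ]
  expect_true(all(count_58s(pars, vc)$n_58s == 1L))
  cats <- d$records[d$records$truth_class == "concatemer", ]
  k <- lengths(d$truth$parent_ids[match(cats$id, d$truth$read_id)])
  expect_equal(count_58s(cats, vc)$n_58s, unname(k))
  set.seed(85)
  noise <- amplicon_tbl(sprintf("x%d", 1:5), replicate(5, rnd_dna(700)))
  expect_true(all(count_58s(noise, vc)$n_58s == 0L))
})

test_that("fn_structure_report stratifies lengths by 5.8S multiplicity", {
  fn <- tibble::tibble(
    id = sprintf("f%02d", 1:12),
    seq = strrep("A", c(rep(1200, 10), rep(500, 2))),
    n_58s = c(rep(2L, 10), rep(1L, 2))
  )
  rep <- fn_structure_report(fn)
  expect_equal(rep$summary$frac_multi_58s, 10 / 12)
  expect_equal(rep$summary$median_len_multi, 1200)
  expect_equal(rep$summary$median_len_single, 500)
  empty <- fn_structure_report(fn[0, ])
  expect_equal(empty$summary$n, 0L)
  expect_equal(nrow(empty$per_read), 0)
})
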