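small_cc <- function(...) {
  community_config(n_species = 5, per_species_reads = c(20L, 30L),
                   its1_length = c(60L, 100L), its2_length = c(60L, 100L),
                   seed = 41L, ...)
}

test_that("template generation is deterministic and tiles the regions", {
  cc <- small_cc()
  t1 <- make_templates(cc)
  t2 <- make_templates(cc)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 5)
  expect_true(all(t1$its1_start == 1))
  expect_true(all(t1$r58s_start == t1$its1_end + 1))
  expect_true(all(t1$its2_start == t1$r58s_end + 1))
  expect_true(all(t1$its2_end == nchar(t1$seq)))
  expect_true(all(t1$r58s_end - t1$r58s_start + 1 == cc$r58s_length))
})

test_that("per-species 5.8S stays near the community consensus", {
  cc <- small_cc()
  tpl <- make_templates(cc)
  cons <- attr(tpl, "r58s_consensus")
  for (i in seq_len(nrow(tpl))) {
    r58 <- substr(tpl$seq[i], tpl$r58s_start[i], tpl$r58s_end[i])
    idf <- mean(strsplit(r58, "")[[1]] == strsplit(cons, "")[[1]])
    expect_gte(idf, 1 - cc$d58 - 0.01)
  }
})

test_that("read counts fall in the configured range, reproducibly", {
  cc <- small_cc()
  tpl <- make_templates(cc)
  n1 <- sample_abundances(tpl, cc)
  n2 <- sample_abundances(tpl, cc)
  expect_identical(n1, n2)
  expect_true(all(n1$n_reads >= 20 & n1$n_reads <= 30))
  one <- community_config(n_species = 3, per_species_reads = c(5L, 5L), seed = 1L)
  expect_true(all(sample_abundances(make_templates(one), one)$n_reads == 5))
})

test_that("the noiseless limit reproduces templates byte-for-byte", {
  cc <- small_cc(sub_rate = 0, ins_rate = 0, del_rate = 0, junk_fraction = 0)
  tpl <- make_templates(cc)
  reads <- simulate_reads(tpl, sample_abundances(tpl, cc), cc)
  expect_true(all(reads$seq == tpl$seq[match(reads$template_id, tpl$id)]))
  # and the whole FASTQ is reproducible under the seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(simulate_reads(tpl, sample_abundances(tpl, cc), cc), f1)
  write_fastq(simulate_reads(tpl, sample_abundances(tpl, cc), cc), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("realized substitution rate concentrates around the configured rate", {
  cc <- community_config(n_species = 4, per_species_reads = c(15L, 15L),
                         its1_length = c(80L, 120L), its2_length = c(80L, 120L),
                         sub_rate = 0.01, ins_rate = 0, del_rate = 0,
                         junk_fraction = 0, seed = 42L)
  tpl <- make_templates(cc)
  reads <- simulate_reads(tpl, sample_abundances(tpl, cc), cc)
  tplseq <- tpl$seq[match(reads$template_id, tpl$id)]
  mism <- mapply(function(r, t) sum(strsplit(r, "")[[1]] != strsplit(t, "")[[1]]),
                 reads$seq, tplseq)
  total <- sum(nchar(reads$seq))
  expect_gte(total, 10000)
  frac <- sum(mism) / total
  expect_gte(frac, 0.007)   # 3-sigma binomial band around 0.01
  expect_lte(frac, 0.013)
})

test_that("maxEE filtering removes close to the configured junk fraction", {
  cc <- community_config(n_species = 6, per_species_reads = c(80L, 120L),
                         its1_length = c(90L, 150L), its2_length = c(90L, 150L),
                         junk_fraction = 0.05, seed = 43L)
  tpl <- make_templates(cc)
  reads <- simulate_reads(tpl, sample_abundances(tpl, cc), cc)
  removed <- nrow(maxee_filter(reads, 1)$discarded) / nrow(reads)
  expect_lt(abs(removed - cc$junk_fraction), 0.02)
})
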