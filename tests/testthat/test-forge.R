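# a small but fully eligible parent pool with template annotations
forge_fixture <- function(seed = 51L) {
  set.seed(seed)
  cc <- community_config(n_species = 6, per_species_reads = c(10L, 10L),
                         its1_length = c(80L, 120L), its2_length = c(80L, 120L),
                         seed = seed)
  tpl <- make_templates(cc)
  list(cc = cc, tpl = tpl)
}

test_that("forged chimeras respect length bounds, regions, and abundance rule", {
  fx <- forge_fixture()
  tpl <- fx$tpl
  config <- forge_config(seed = 1L)
  set.seed(52)
  draws <- integer(0)
  for (i in 1:200) {
    pr <- sample(nrow(tpl), 2)
    pa <- tibble::tibble(id = tpl$id[pr[1]], seq = tpl$seq[pr[1]], abundance = 10L)
    pb <- tibble::tibble(id = tpl$id[pr[2]], seq = tpl$seq[pr[2]], abundance = 6L)
    ch <- forge_chimera(pa, pb, tpl[pr[1], ], tpl[pr[2], ], config,
                        id = sprintf("c%03d", i))
    if (is.null(ch)) next   # length constraint unsatisfiable for this pair
    r <- nchar(ch$seq) / nchar(c(pa$seq, pb$seq))
    expect_true(all(r >= 0.7 & r <= 1.1))
    # breakpoint lies inside an annotated region of parent a
    bp <- ch$breakpoints[[1]][1]
    expect_gte(bp, 1); expect_lt(bp, nchar(pa$seq))
    # reconstruction from the truth record
    parents <- tibble::tibble(id = c(pa$id, pb$id), seq = c(pa$seq, pb$seq))
    expect_equal(reconstruct_artifact(ch, parents), ch$seq)
    draws <- c(draws, ch$abundance)
  }
  # abundance rule: Uniform{1..floor(min(10,6)/2)} = {1,2,3}
  expect_setequal(sort(unique(draws)), 1:3)
})

test_that("concatemers join full parents and carry k complete 5.8S regions", {
  fx <- forge_fixture()
  tpl <- fx$tpl
  vc <- validation_config(r58s_model = attr(fx$tpl, "r58s_consensus"))
  set.seed(53)
  for (k in 2:3) {
    pr <- sample(nrow(tpl), k)
    parents <- tibble::tibble(id = tpl$id[pr], seq = tpl$seq[pr], abundance = 1L)
    cat <- forge_concatemer(parents, forge_config(seed = 1L), id = "k1")
    expect_equal(nchar(cat$seq), sum(nchar(parents$seq)))
    expect_equal(cat$abundance, 1L)
    expect_equal(reconstruct_artifact(cat, parents), cat$seq)
    expect_equal(count_58s(cat, vc)$n_58s, k)
  }
})

test_that("spike_dataset hits the configured artifact fractions and is reproducible", {
  cc <- community_config(n_species = 8, per_species_reads = c(60L, 80L),
                         its1_length = c(80L, 120L), its2_length = c(80L, 120L),
                         sub_rate = 0.001, ins_rate = 0.001, del_rate = 0.001,
                         junk_fraction = 0, seed = 54L)
  tpl <- make_templates(cc)
  reads <- simulate_reads(tpl, sample_abundances(tpl, cc), cc)
  config <- forge_config(seed = 55L)
  sp <- spike_dataset(reads, tpl, config)
  n_total <- nrow(sp$records)
  n_chim <- sum(sp$truth$klass == "pcr_chimera")
  expect_lt(abs(n_chim / n_total - config$chimera_fraction), 0.002)
  expect_lte(abs(n_chim - round(config$chimera_fraction * n_total)), 1)
  # truth covers every record
  expect_setequal(sp$truth$read_id, sp$records$id)
  # byte-level determinism of the spiked set
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(sp$records[, c("id", "seq", "abundance")], f1, with_size = TRUE)
  sp2 <- spike_dataset(reads, tpl, config)
  write_fasta(sp2$records[, c("id", "seq", "abundance")], f2, with_size = TRUE)
  expect_identical(readLines(f1), readLines(f2))
  # abundance rule holds against the dereplicated parent pool
  chim_truth <- sp$truth[sp$truth$klass == "pcr_chimera", ]
  ab_of <- function(ids) sp$parents$abundance[match(ids, sp$parents$id)]
  ch_ab <- sp$records$abundance[match(chim_truth$read_id, sp$records$id)]
  min_par <- vapply(chim_truth$parent_ids, function(p) min(ab_of(p)), numeric(1))
  expect_true(all(ch_ab <= min_par / 2))
})

test_that("concatemers are longer than parental reads on a generated set", {
  d <- bench_dataset()
  len <- nchar(d$records$seq)
  kl <- d$records$truth_class
  expect_gt(median(len[kl == "concatemer"]), median(len[kl == "parental"]))
})

test_that("spiking fails cleanly without eligible parents", {
  cc <- community_config(n_species = 3, per_species_reads = c(3L, 3L),
                         junk_fraction = 0, seed = 56L)
  tpl <- make_templates(cc)
  reads <- simulate_reads(tpl, sample_abundances(tpl, cc), cc)
  # at 3 reads/species there are essentially never 2 exact copies
  expect_error(spike_dataset(reads, tpl, forge_config(seed = 1L)),
               "fewer than 2 species")
})
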