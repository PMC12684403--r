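# shared fixtures, built once per test run on first use

.fx <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  at <- sample(length(v), k)
  for (i in at) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# the benchmark community: ~5,400 reads over 24 species, error rates and
# artifact fractions at the study defaults
bench_config <- function() {
  community_config(
    n_species = 24, per_species_reads = c(180L, 280L),
    its1_length = c(90L, 180L), its2_length = c(100L, 200L), seed = 101L
  )
}

bench_dataset <- function() {
  memo("bench_dataset", function() {
    cc <- bench_config()
    tpl <- make_templates(cc)
    reads <- simulate_reads(tpl, sample_abundances(tpl, cc), cc)
    kept <- maxee_filter(reads, 1)$kept
    sp <- spike_dataset(kept, tpl, forge_config(seed = 102L))
    derep <- dereplicate(sp$records[, c("id", "seq", "abundance")])
    list(config = cc, templates = tpl, reads = reads, kept = kept,
         records = sp$records, truth = sp$truth, parents = sp$parents,
         derep = derep, consensus = attr(tpl, "r58s_consensus"))
  })
}

bench_calls <- function() {
  memo("bench_calls", function() {
    detect_chimeras(bench_dataset()$derep, detector_params())
  })
}

# small random detection instance: templates + noisy reads + one forged
# two-parent chimera (ids: tNN templates, nNN noise, chimX artifact)
small_instance <- function(n_templates = NULL, len = NULL) {
  nt <- if (is.null(n_templates)) sample(2:4, 1) else n_templates
  L <- if (is.null(len)) sample(60:120, 1) else len
  tpls <- replicate(nt, rnd_dna(L))
  rows <- list()
  for (t in seq_len(nt)) {
    rows[[t]] <- tibble::tibble(id = sprintf("t%02d", t), seq = tpls[t],
                                abundance = sample(4:12, 1))
  }
  for (j in seq_len(sample(2:4, 1))) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = sprintf("n%02d", j),
      seq = mutate_seq(tpls[sample(nt, 1)], sample(1:3, 1)),
      abundance = 1L
    )
  }
  pr <- sample(nt, 2)
  bp <- sample(20:(L - 20), 1)
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = "chimX",
    seq = paste0(substr(tpls[pr[1]], 1, bp), substr(tpls[pr[2]], bp + 1, L)),
    abundance = sample(1:2, 1)
  )
  out <- dplyr::bind_rows(rows)
  out[!duplicated(out$seq), ]
}

# independent affine-gap global DP (score only); gap of length k costs
# open + k * extend, end gaps charged, N mismatches everything
nw_score_oracle <- function(a, b, match = 1, mismatch = -1,
                            open = 1, extend = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  sub <- function(x, y) {
    if (x == "N" || y == "N") mismatch else if (x == y) match else mismatch
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- sub(av[i - 1], bv[j - 1])
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                   Y[i - 1, j] - open - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, X[i, j - 1] - open - extend,
                   Y[i, j - 1] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# chimeras whose minority segment is a real fraction of the read; a chimera
# with a tiny foreign tail is >99% identical to one parent and is
# indistinguishable from it by any identity rule
balanced_chimeras <- function(d, n = 25, min_frac = 0.15) {
  tr <- d$truth[d$truth$klass == "pcr_chimera", ]
  len <- nchar(d$records$seq[match(tr$read_id, d$records$id)])
  frac <- mapply(function(bp, L) min(diff(c(0, bp, L))) / L,
                 tr$breakpoints, len)
  ids <- utils::head(tr$read_id[frac >= min_frac], n)
  d$records[match(ids, d$records$id), c("id", "seq")]
}
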