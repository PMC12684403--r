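#' Configuration for a synthetic full-ITS community
#'
#' Defines the study conditions for template generation and PacBio-like read
#' simulation: a community of species-level ITS1-5.8S-ITS2 templates sharing
#' a conserved 5.8S (per-species divergence `d58` from a common consensus)
#' with fast-evolving, species-independent ITS1/ITS2 spacers, read counts
#' drawn uniformly per species, and an independent per-base error channel
#' (substitution / insertion / deletion). A configurable fraction of reads is
#' emitted with globally low quality to exercise expected-error filtering.
#'
#' @param n_species Number of species templates (default 186).
#' @param per_species_reads Inclusive integer range of reads per species
#'   (default `c(1000, 9000)`).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities
#'   (defaults 0.002, 0.0025, 0.0025).
#' @param d58 Per-base divergence of each species' 5.8S from the community
#'   consensus (default 0.03).
#' @param r58s_length Length of the 5.8S region (default 157).
#' @param its1_length,its2_length Inclusive length ranges for ITS1 and ITS2
#'   (defaults `c(120, 400)` and `c(150, 420)`).
#' @param junk_fraction Fraction of reads emitted with globally low quality
#'   (default 0.05).
#' @param high_q Inclusive Phred range for error-free bases (default
#'   `c(40, 93)`; capped at 93).
#' @param error_q Phred score emitted for bases realized through the error
#'   channel (default 13).
#' @param junk_q Phred score for low-quality junk reads (default 7).
#' @param seed Integer seed; every downstream generator is deterministic
#'   under it.
#' @return A `community_config` list.
#' @export
community_config <- function(n_species = 186L, per_species_reads = c(1000L, 9000L),
                             sub_rate = 0.002, ins_rate = 0.0025, del_rate = 0.0025,
                             d58 = 0.03, r58s_length = 157L,
                             its1_length = c(120L, 400L), its2_length = c(150L, 420L),
                             junk_fraction = 0.05, high_q = c(40L, 93L),
                             error_q = 13L, junk_q = 7L, seed = 1L) {
  stopifnot(n_species >= 2, length(per_species_reads) == 2,
            per_species_reads[1] >= 1, per_species_reads[2] >= per_species_reads[1],
            sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, d58 >= 0, d58 < 1,
            junk_fraction >= 0, junk_fraction < 1, high_q[2] <= 93)
  structure(list(
    n_species = as.integer(n_species),
    per_species_reads = as.integer(per_species_reads),
    sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
    d58 = d58, r58s_length = as.integer(r58s_length),
    its1_length = as.integer(its1_length), its2_length = as.integer(its2_length),
    junk_fraction = junk_fraction, high_q = as.integer(high_q),
    error_q = as.integer(error_q), junk_q = as.integer(junk_q),
    seed = as.integer(seed)
  ), class = "community_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# uniform integer draw on an inclusive range (safe when lo == hi, unlike
# sample(lo:hi, ...))
.rint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

.mutate_subs <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

#' Generate species-level full-ITS templates
#'
#' Produces `n_species` templates tiling ITS1, 5.8S and ITS2 exactly: one
#' shared 5.8S consensus is drawn once and mutated per species at rate `d58`
#' (so all templates stay highly similar in 5.8S), while ITS1/ITS2 are drawn
#' independently per species with uniform base composition (inter-species ITS
#' identity is therefore near the 25% random expectation). Deterministic
#' under `config$seed`.
#'
#' @param config A [community_config()].
#' @return A tibble: `id`, `seq`, `taxon`, 1-based inclusive spans
#'   `its1_start/its1_end`, `r58s_start/r58s_end`, `its2_start/its2_end`,
#'   with the 5.8S consensus in attribute `r58s_consensus`.
#' @export
make_templates <- function(config) {
  withr::with_seed(config$seed, {
    consensus <- .rand_dna(config$r58s_length)
    rows <- purrr::map(seq_len(config$n_species), function(i) {
      l1 <- .rint(1L, config$its1_length[1], config$its1_length[2])
      l2 <- .rint(1L, config$its2_length[1], config$its2_length[2])
      r58 <- .mutate_subs(consensus, config$d58)
      tibble(
        id = sprintf("sp%03d", i),
        seq = paste0(.rand_dna(l1), r58, .rand_dna(l2)),
        taxon = sprintf("Species_%03d", i),
        its1_start = 1L, its1_end = l1,
        r58s_start = l1 + 1L, r58s_end = l1 + config$r58s_length,
        its2_start = l1 + config$r58s_length + 1L,
        its2_end = l1 + config$r58s_length + l2
      )
    })
    out <- bind_rows(rows)
    attr(out, "r58s_consensus") <- consensus
    out
  })
}

#' Draw per-species read counts
#'
#' Each species receives a read count drawn uniformly (inclusive) from
#' `config$per_species_reads`; deterministic under `config$seed`.
#'
#' @param templates Output of [make_templates()].
#' @param config A [community_config()].
#' @return A tibble `id`, `n_reads`.
#' @export
sample_abundances <- function(templates, config) {
  withr::with_seed(config$seed + 1L, {
    rng <- config$per_species_reads
    tibble(id = templates$id,
           n_reads = .rint(nrow(templates), rng[1], rng[2]))
  })
}

# one read through the independent per-base error channel; returns seq + quals
.channel_read <- function(tplv, config) {
  acgt <- c("A", "C", "G", "T")
  # column b of .alt: the three bases that are not acgt[b]
  alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                nrow = 3)
  n <- length(tplv)
  keep <- runif(n) >= config$del_rate
  sub <- keep & (runif(n) < config$sub_rate)
  ins <- runif(n) < config$ins_rate
  emit <- tplv
  qual <- .rint(n, config$high_q[1], config$high_q[2])
  if (any(sub)) {
    at <- which(sub)
    emit[at] <- alt[cbind(sample(3L, length(at), replace = TRUE),
                          match(tplv[at], acgt))]
    qual[at] <- config$error_q
  }
  nb <- as.integer(keep) + as.integer(ins)
  total <- sum(nb)
  pos <- cumsum(nb)
  out_b <- character(total); out_q <- integer(total)
  kidx <- (pos - as.integer(ins))[keep]
  out_b[kidx] <- emit[keep]; out_q[kidx] <- qual[keep]
  if (any(ins)) {
    iidx <- pos[ins]
    out_b[iidx] <- sample(acgt, sum(ins), replace = TRUE)
    out_q[iidx] <- config$error_q
  }
  list(seq = paste(out_b, collapse = ""), quals = out_q)
}

#' Simulate PacBio-like reads from templates
#'
#' Each read is its template passed through an independent per-base error
#' channel (substitution, insertion, deletion at the configured rates).
#' Error-free bases get high Phred scores drawn from `config$high_q` (capped
#' at 93); bases realized through the channel get `config$error_q`. A
#' `config$junk_fraction` of reads is emitted with all scores at
#' `config$junk_q` so that maxEE filtering has something to remove.
#' Deterministic under `config$seed`.
#'
#' @param templates Output of [make_templates()].
#' @param counts Output of [sample_abundances()] (columns `id`, `n_reads`).
#' @param config A [community_config()].
#' @return An amplicon tibble with `quals` and truth columns
#'   (`truth_class = "parental"`, `template_id`).
#' @export
simulate_reads <- function(templates, counts, config) {
  stopifnot(all(counts$n_reads >= 1))
  withr::with_seed(config$seed + 2L, {
    counts <- counts[match(templates$id, counts$id), ]
    rows <- vector("list", nrow(templates))
    for (t in seq_len(nrow(templates))) {
      tplv <- strsplit(templates$seq[t], "")[[1]]
      nr <- counts$n_reads[t]
      seqs <- character(nr); quals <- vector("list", nr)
      for (r in seq_len(nr)) {
        rd <- .channel_read(tplv, config)
        seqs[r] <- rd$seq; quals[[r]] <- rd$quals
      }
      junk <- runif(nr) < config$junk_fraction
      for (r in which(junk)) quals[[r]] <- rep(config$junk_q, length(quals[[r]]))
      rows[[t]] <- tibble(
        id = sprintf("%s_r%05d", templates$id[t], seq_len(nr)),
        seq = seqs, abundance = 1L, sample_id = "sim",
        quals = quals, truth_class = "parental", template_id = templates$id[t]
      )
    }
    validate_amplicons(bind_rows(rows))
  })
}
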