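#' Configuration for planting ground-truth artifacts
#'
#' Controls the PCR-chimera and concatemer spiking of a simulated read set.
#' Breakpoints are drawn region-wise ("ITS region-specific probabilities"):
#' a region is picked by `region_weights`, then a breakpoint is drawn
#' uniformly inside that region of each parent. Chimera length is constrained
#' relative to both parents, and chimera abundance is drawn from
#' `Uniform{1 .. floor(min(parent abundances) / 2)}` so chimeras never
#' dominate their parents (abundance skew of at least 2 is guaranteed at
#' truth level).
#'
#' @param chimera_fraction Fraction of the final read set that is PCR
#'   chimeras (default 0.062).
#' @param region_weights Named weights for ITS1 / 5.8S / ITS2 breakpoint
#'   placement, summing to 1 (default 0.4 / 0.2 / 0.4).
#' @param three_parent_fraction Fraction of chimeras built from three parents
#'   (default 0.05).
#' @param rc_segment_fraction Probability that a chimera's 3' segment is
#'   reverse-complemented (default 0.02) — the artifact class breakpoint
#'   detectors are known to miss.
#' @param length_bounds Allowed `len(child)/len(parent)` ratio range against
#'   both parents (default `c(0.7, 1.1)`).
#' @param concatemer_fraction Fraction of the final read set that is
#'   library-prep concatemers (default 0.005).
#' @param concatemer_copies Inclusive range of full amplicons joined per
#'   concatemer (default `c(2, 3)`).
#' @param seed Integer seed.
#' @return A `forge_config` list.
#' @export
forge_config <- function(chimera_fraction = 0.062,
                         region_weights = c(ITS1 = 0.4, `5.8S` = 0.2, ITS2 = 0.4),
                         three_parent_fraction = 0.05,
                         rc_segment_fraction = 0.02,
                         length_bounds = c(0.7, 1.1),
                         concatemer_fraction = 0.005,
                         concatemer_copies = c(2L, 3L),
                         seed = 1L) {
  stopifnot(chimera_fraction > 0, chimera_fraction < 0.5,
            abs(sum(region_weights) - 1) < 1e-9, all(region_weights >= 0),
            three_parent_fraction >= 0, three_parent_fraction < 1,
            rc_segment_fraction >= 0, rc_segment_fraction < 1,
            length_bounds[1] > 0, length_bounds[2] >= length_bounds[1],
            concatemer_fraction >= 0, concatemer_fraction < 1)
  structure(list(
    chimera_fraction = chimera_fraction, region_weights = region_weights,
    three_parent_fraction = three_parent_fraction,
    rc_segment_fraction = rc_segment_fraction,
    length_bounds = length_bounds,
    concatemer_fraction = concatemer_fraction,
    concatemer_copies = as.integer(concatemer_copies),
    seed = as.integer(seed)
  ), class = "forge_config")
}

# draw a breakpoint inside one region of a template annotation row.
# returns the 1-based position AFTER which the sequence is cut (so the
# prefix is seq[1..bp]); guaranteed interior.
.region_breakpoint <- function(regions, region) {
  span <- switch(region,
    ITS1 = c(regions$its1_start, regions$its1_end),
    `5.8S` = c(regions$r58s_start, regions$r58s_end),
    ITS2 = c(regions$its2_start, regions$its2_end)
  )
  lo <- max(1L, span[1]); hi <- min(span[2], regions$its2_end - 1L)
  .rint(1L, lo, hi)
}

#' Forge a two-parent PCR chimera
#'
#' Picks a region by `config$region_weights`, draws a breakpoint uniformly
#' within that region of each parent, and joins `parent_a[1..bp_a]` with the
#' suffix of `parent_b` starting after `bp_b`. Breakpoints are resampled (up
#' to 100 attempts) until the child/parent length ratio lies within
#' `config$length_bounds` for both parents; an unsatisfiable pair returns
#' `NULL`. With probability `config$rc_segment_fraction` the 3' segment is
#' reverse-complemented. Abundance follows the uniform half-min-parent rule.
#' Draws from the current RNG state.
#'
#' @param parent_a,parent_b One-row amplicon tibbles (distinct, parental).
#' @param regions_a,regions_b Region annotation rows (template rows from
#'   [make_templates()]) for the two parents.
#' @param config A [forge_config()].
#' @param id Id for the child record.
#' @return A one-row amplicon tibble with truth columns, or `NULL` if the
#'   length constraint was unsatisfiable in 100 attempts.
#' @export
forge_chimera <- function(parent_a, parent_b, regions_a, regions_b, config,
                          id = "chimera") {
  stopifnot(parent_a$id != parent_b$id)
  la <- nchar(parent_a$seq); lb <- nchar(parent_b$seq)
  for (attempt in seq_len(100)) {
    region <- sample(names(config$region_weights), 1,
                     prob = config$region_weights)
    bp_a <- .region_breakpoint(regions_a, region)
    bp_b <- .region_breakpoint(regions_b, region)
    child_len <- bp_a + (lb - bp_b)
    r <- child_len / c(la, lb)
    if (all(r >= config$length_bounds[1]) && all(r <= config$length_bounds[2])) {
      left <- substr(parent_a$seq, 1, bp_a)
      right <- substr(parent_b$seq, bp_b + 1, lb)
      rc <- runif(1) < config$rc_segment_fraction
      if (rc) right <- revcomp(right)
      ab_max <- floor(min(parent_a$abundance, parent_b$abundance) / 2)
      if (ab_max < 1) abort("forge_chimera: parent abundances too small")
      return(tibble(
        id = id, seq = paste0(left, right),
        abundance = as.integer(sample(ab_max, 1)),
        sample_id = if ("sample_id" %in% names(parent_a))
          parent_a$sample_id else NA_character_,
        truth_class = "pcr_chimera",
        parent_ids = list(c(parent_a$id, parent_b$id)),
        breakpoints = list(bp_a),
        rc_segments = list(c(FALSE, rc)),
        parent_starts = list(c(1L, bp_b + 1L))
      ))
    }
  }
  NULL
}

# three-parent chimera: a-prefix + b-middle + c-suffix, each boundary drawn
# region-wise; returns NULL if constraints unsatisfiable.
.forge_chimera3 <- function(parents, regions, config, id) {
  l <- nchar(parents$seq)
  for (attempt in seq_len(100)) {
    regs <- sample(names(config$region_weights), 2, replace = TRUE,
                   prob = config$region_weights)
    regs <- regs[order(match(regs, c("ITS1", "5.8S", "ITS2")))]
    bp_a <- .region_breakpoint(regions[1, ], regs[1])
    b1 <- .region_breakpoint(regions[2, ], regs[1])
    b2 <- .region_breakpoint(regions[2, ], regs[2])
    if (b2 <= b1) next
    bp_c <- .region_breakpoint(regions[3, ], regs[2])
    child_len <- bp_a + (b2 - b1) + (l[3] - bp_c)
    r <- child_len / l
    if (any(r < config$length_bounds[1]) || any(r > config$length_bounds[2])) next
    mid <- substr(parents$seq[2], b1 + 1, b2)
    right <- substr(parents$seq[3], bp_c + 1, l[3])
    rc <- runif(1) < config$rc_segment_fraction
    if (rc) right <- revcomp(right)
    ab_max <- floor(min(parents$abundance) / 2)
    if (ab_max < 1) abort("forge_chimera: parent abundances too small")
    return(tibble(
      id = id,
      seq = paste0(substr(parents$seq[1], 1, bp_a), mid, right),
      abundance = as.integer(sample(ab_max, 1)),
      sample_id = if ("sample_id" %in% names(parents))
        parents$sample_id[1] else NA_character_,
      truth_class = "pcr_chimera",
      parent_ids = list(parents$id),
      breakpoints = list(c(bp_a, bp_a + (b2 - b1))),
      rc_segments = list(c(FALSE, FALSE, rc)),
      parent_starts = list(c(1L, b1 + 1L, bp_c + 1L))
    ))
  }
  NULL
}

#' Forge a library-preparation concatemer
#'
#' Joins two or three complete parent amplicons end-to-end (no truncation),
#' so the child contains one full 5.8S region per parent. Abundance 1.
#'
#' @param parents Amplicon tibble of 2-3 rows.
#' @param config A [forge_config()] (unused fields ignored).
#' @param id Id for the child record.
#' @return A one-row amplicon tibble with truth columns.
#' @export
forge_concatemer <- function(parents, config, id = "concatemer") {
  stopifnot(nrow(parents) >= 2, nrow(parents) <= 3)
  lens <- nchar(parents$seq)
  tibble(
    id = id, seq = paste(parents$seq, collapse = ""), abundance = 1L,
    sample_id = if ("sample_id" %in% names(parents))
      parents$sample_id[1] else NA_character_,
    truth_class = "concatemer",
    parent_ids = list(parents$id),
    breakpoints = list(cumsum(lens)[-length(lens)]),
    rc_segments = list(rep(FALSE, nrow(parents))),
    parent_starts = list(rep(1L, nrow(parents)))
  )
}

#' Reconstruct an artifact from its truth record
#'
#' Rebuilds a chimera or concatemer sequence from its parents, breakpoints,
#' per-segment parent start positions and reverse-complement flags — the
#' self-consistency oracle run over every generated dataset.
#'
#' @param truth_row One row of a truth tibble (list columns intact).
#' @param parents Amplicon table containing every parent id.
#' @return The reconstructed sequence string.
#' @export
reconstruct_artifact <- function(truth_row, parents) {
  pid <- truth_row$parent_ids[[1]]
  bps <- truth_row$breakpoints[[1]]
  rc <- truth_row$rc_segments[[1]]
  pst <- truth_row$parent_starts[[1]]
  seg_end <- c(bps, NA)
  seg_start <- c(1L, bps + 1L)
  segs <- character(length(pid))
  for (k in seq_along(pid)) {
    pseq <- parents$seq[match(pid[k], parents$id)]
    if (is.na(pseq)) abort(paste0("reconstruct_artifact: unknown parent ", pid[k]))
    len_k <- if (k < length(pid)) seg_end[k] - seg_start[k] + 1L else
      nchar(pseq) - pst[k] + 1L
    piece <- substr(pseq, pst[k], pst[k] + len_k - 1L)
    if (rc[k]) piece <- revcomp(piece)
    segs[k] <- piece
  }
  paste(segs, collapse = "")
}

#' Spike a simulated read set with chimeras and concatemers
#'
#' Plants ground-truth artifacts into a parental read set. The number of PCR
#' chimeras is `round(chimera_fraction * final_total)` (within 1) and
#' concatemers follow `concatemer_fraction`. Chimera parents are drawn from
#' the *clean* reads — reads whose sequence exactly matches a template — via
#' dereplication, so parent abundances (exact-copy counts) are well defined
#' and the abundance rule guarantees detectability at truth level; parents
#' are required to come from distinct templates with at least 2 exact copies
#' each. Concatemer parents are arbitrary reads. Output order is shuffled
#' deterministically under `config$seed`.
#'
#' @param reads Parental amplicon tibble from [simulate_reads()].
#' @param templates Output of [make_templates()].
#' @param config A [forge_config()].
#' @return A list: `records` (spiked amplicon tibble, truth columns
#'   included), `truth` (truth tibble covering every read), and `parents`
#'   (the dereplicated clean-parent pool used for forging).
#' @export
spike_dataset <- function(reads, templates, config) {
  stopifnot(all(reads$truth_class == "parental"))
  withr::with_seed(config$seed, {
    derep <- dereplicate(reads[, c("id", "seq", "abundance")])
    pool <- derep |>
      mutate(template_id = templates$id[match(seq, templates$seq)]) |>
      filter(!is.na(.data$template_id), abundance >= 2L)
    if (length(unique(pool$template_id)) < 2) {
      abort("spike_dataset: fewer than 2 species with clean parent reads")
    }
    n_par <- nrow(reads)
    total <- n_par / (1 - config$chimera_fraction - config$concatemer_fraction)
    n_ch <- round(config$chimera_fraction * total)
    n_cat <- round(config$concatemer_fraction * total)

    chims <- vector("list", n_ch)
    made <- 0L; attempts <- 0L
    while (made < n_ch) {
      attempts <- attempts + 1L
      if (attempts > 50L * n_ch) {
        abort("spike_dataset: could not forge enough chimeras under the length constraints")
      }
      k <- if (runif(1) < config$three_parent_fraction &&
               length(unique(pool$template_id)) >= 3) 3L else 2L
      tpls <- sample(unique(pool$template_id), k)
      pick <- purrr::map_int(tpls, function(tp) {
        cand <- which(pool$template_id == tp)
        cand[sample.int(length(cand), 1)]
      })
      prs <- pool[pick, ]
      regs <- templates[match(tpls, templates$id), ]
      child <- if (k == 2L) {
        forge_chimera(prs[1, ], prs[2, ], regs[1, ], regs[2, ], config,
                      id = sprintf("chim%05d", made + 1L))
      } else {
        .forge_chimera3(prs, regs, config, id = sprintf("chim%05d", made + 1L))
      }
      if (is.null(child)) next
      made <- made + 1L
      chims[[made]] <- child
    }
    chims <- bind_rows(chims)

    # each concatemer gets a distinct species combination, as holds by chance
    # at study scale (hundreds of species); twin concatemers would shadow
    # each other in downstream split-HSP validation
    seen_combo <- character(0)
    cats <- purrr::map(seq_len(n_cat), function(i) {
      for (attempt in 1:100) {
        k <- .rint(1L, config$concatemer_copies[1], config$concatemer_copies[2])
        pick <- sample.int(n_par, k)
        combo <- paste(sort(unique(reads$template_id[pick])), collapse = "+")
        if (!combo %in% seen_combo) {
          seen_combo <<- c(seen_combo, combo)
          return(forge_concatemer(reads[pick, ], config,
                                  id = sprintf("concat%04d", i)))
        }
      }
      abort("spike_dataset: could not draw distinct concatemer species sets")
    })
    cats <- bind_rows(cats)

    par_rec <- reads |>
      mutate(parent_ids = list(character(0)), breakpoints = list(integer(0)),
             rc_segments = list(logical(0)), parent_starts = list(integer(0)))
    keep_cols <- c("id", "seq", "abundance", "sample_id", "quals",
                   "truth_class", "parent_ids", "breakpoints", "rc_segments",
                   "parent_starts")
    # artifacts are planted post-quality-filtering: give them a flat high-Q
    # profile so they survive maxEE, as the study design requires
    add_quals <- function(x) {
      if (nrow(x) == 0) return(x)
      x$quals <- purrr::map(nchar(x$seq), function(n) rep(40L, n))
      x
    }
    chims <- add_quals(chims); cats <- add_quals(cats)
    if (!"quals" %in% names(par_rec)) {
      keep_cols <- setdiff(keep_cols, "quals")
    }
    all_rec <- bind_rows(par_rec[, keep_cols],
                         if (nrow(chims)) chims[, keep_cols],
                         if (nrow(cats)) cats[, keep_cols])
    all_rec <- all_rec[sample.int(nrow(all_rec)), ]
    truth <- tibble(
      read_id = all_rec$id, klass = all_rec$truth_class,
      parent_ids = all_rec$parent_ids, breakpoints = all_rec$breakpoints,
      rc_segments = all_rec$rc_segments, parent_starts = all_rec$parent_starts
    )
    list(records = validate_amplicons(all_rec), truth = truth, parents = pool)
  })
}
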