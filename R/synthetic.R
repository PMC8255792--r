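# Deterministic fixtures (sequenced-allele catalogue, allele length
# spectrum) and seeded synthetic cohorts.

.BLOCK_T3 <- c("TCTG", "CCTG", "TCTG")
.BLOCK_G3 <- c("GCTG", "CCTG", "TCTG")
.BLOCK_T5 <- c("TCTG", "CCTG", "TCTG", "CCTG", "TCTG")
.BLOCK_G5 <- c("GCTG", "CCTG", "TCTG", "CCTG", "TCTG")

# deterministic (v, w) grid inside the observed polymorphic ranges,
# used to spread catalogue entries whose flanks are not individually
# printed; the two worked full motifs are excluded so their multiplicity
# stays exactly as reported.
catalogue_vw_grid <- function() {
  g <- expand.grid(v = 14:26, w = 7:11)
  g[!(g$v == 21 & g$w == 9) & !(g$v == 17 & g$w == 9), ]
}

#' Deterministic catalogue of 103 sequenced healthy-range alleles
#'
#' Reconstructs the sequenced-allele catalogue with the reported
#' composition: 64 alleles with core `(CCTG)5(NCTG)3(CCTG)7` -- of which 9
#' carry the full 138-bp motif `(TG)21(TCTG)9(...)` and 9 the 130-bp
#' motif `(TG)17(TCTG)9(...)` -- 21 with core `(CCTG)6(NCTG)3(CCTG)7`, 6
#' further three-tetramer-window alleles (including the shortest, 108-bp,
#' structure), 7 five-tetramer-window alleles, and 5 uninterrupted
#' alleles (including `(CCTG)10`, `(CCTG)12` and the longest, 168-bp,
#' `(TG)18(TCTG)10(CCTG)23`). Totals: 98 interrupted + 5 uninterrupted.
#'
#' Flank sizes (`v`, `w`) and window variants (`TCTG` vs `GCTG` lead) of
#' alleles that are not individually printed are fixed, documented,
#' grammar-valid choices inside the observed ranges (`v` 14--26, `w`
#' 7--11); the construction is fully deterministic (bit-identical across
#' runs).
#'
#' @return A named list of 103 [motif_decomposition()] objects
#'   (ids `cat001`...`cat103`).
#' @export
#' @examples
#' cat <- build_sequenced_catalogue()
#' length(cat)  # 103
build_sequenced_catalogue <- function() {
  md <- motif_decomposition
  out <- list()
  add <- function(d, times = 1L) {
    for (i in seq_len(times)) out[[length(out) + 1L]] <<- d
  }
  grid <- catalogue_vw_grid()

  # 64 x core (CCTG)5(NCTG)3(CCTG)7: the two printed full motifs at 9 copies
  # each, the other 46 spread over the (v, w) grid
  add(md(21, 9, 5, .BLOCK_T3, 7), 9)   # 138 bp, printed full motif
  add(md(17, 9, 5, .BLOCK_T3, 7), 9)   # 130 bp, printed full motif
  for (i in seq_len(46)) {
    blk <- if (i %% 2L == 1L) .BLOCK_T3 else .BLOCK_G3
    add(md(grid$v[i], grid$w[i], 5, blk, 7))
  }
  # 21 x core (CCTG)6(NCTG)3(CCTG)7 (flanks may reuse grid rows: the core
  # differs, so full-motif tallies cannot collide with the printed motifs)
  for (i in 43:63) {
    blk <- if (i %% 2L == 1L) .BLOCK_T3 else .BLOCK_G3
    add(md(grid$v[i], grid$w[i], 6, blk, 7))
  }
  # 6 further three-tetramer-window cores, incl. the 108-bp shortest allele
  add(md(16, 7, 5, .BLOCK_T3, 4))      # 108 bp, printed structure
  add(md(18, 8, 5, .BLOCK_G3, 8))
  add(md(20, 9, 7, .BLOCK_T3, 7))
  add(md(15, 8, 6, .BLOCK_G3, 4))
  add(md(22, 10, 8, .BLOCK_T3, 6))
  add(md(19, 7, 9, .BLOCK_G3, 5))
  # 7 five-tetramer-window cores
  add(md(18, 9, 6, .BLOCK_T5, 6))
  add(md(19, 8, 5, .BLOCK_G5, 7))
  add(md(16, 9, 6, .BLOCK_T5, 5))
  add(md(21, 8, 7, .BLOCK_G5, 6))
  add(md(17, 10, 5, .BLOCK_T5, 6))
  add(md(20, 9, 6, .BLOCK_G5, 7))
  add(md(15, 9, 6, .BLOCK_T5, 6))
  # 5 uninterrupted alleles
  add(md(18, 10, 23))                  # 168 bp, printed structure
  add(md(18, 9, 10))                   # short uninterrupted (CCTG)10
  add(md(19, 9, 12))                   # short uninterrupted (CCTG)12
  add(md(15, 9, 22))
  add(md(16, 9, 24))

  names(out) <- sprintf("cat%03d", seq_along(out))
  out
}

#' Deterministic 756-chromosome allele length spectrum
#'
#' Reconstructs the healthy-range allele length spectrum from its printed
#' summary: 25 distinct even lengths spanning 108--168 bp with the five
#' printed frequencies fixed exactly (138 bp 21%, 134 bp 13%, 140 bp 11%,
#' 136 bp 10%, 142 bp 7%, converted to counts as `round(p * 756)`). The
#' residual 287 chromosomes are spread over 20 further even lengths
#' (including both endpoints 108 and 168) by largest-remainder assignment
#' under a geometric decay away from the 138-bp mode (ratio 0.7 per 2
#' bp), with a floor of one chromosome per length. The result is unimodal
#' and fully deterministic.
#'
#' @return A [frequency_spectrum()] with 25 lengths and 756 chromosomes.
#' @export
#' @examples
#' s <- build_length_spectrum()
#' attr(s, "total")  # 756
build_length_spectrum <- function() {
  fixed_len <- c(138L, 134L, 140L, 136L, 142L)
  fixed_cnt <- as.integer(round_half_up(c(0.21, 0.13, 0.11, 0.10, 0.07) * 756, 0))
  other_len <- c(108L, 118L, 120L, 122L, 124L, 126L, 128L, 130L, 132L,
                 144L, 146L, 148L, 150L, 152L, 154L, 156L, 158L, 160L, 164L, 168L)
  residual <- 756L - sum(fixed_cnt)
  w <- 0.7^(abs(other_len - 138L) / 2)
  base <- rep(1L, length(other_len))
  quota <- (residual - sum(base)) * w / sum(w)
  cnt <- base + as.integer(floor(quota))
  left <- residual - sum(cnt)
  frac <- quota - floor(quota)
  ord <- order(-frac, other_len)  # largest remainder, ties to smaller length
  cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1L
  frequency_spectrum(c(fixed_len, other_len), c(fixed_cnt, cnt))
}

#' Instantiate an allele length as a grammar-valid decomposition
#'
#' Deterministically maps a tract length in bp to a healthy-range
#' decomposition, reflecting that length variation is mostly absorbed by
#' the `(TG)v` and `(TCTG)w` flanks. Priority: a three-tetramer-window
#' allele with `x` 5--9 and `z` 4--8 (preferring the modal `w = 9`,
#' `x = 5`, `z = 7` core) and `v` solved within 14--26; failing that, a
#' long uninterrupted allele; failing that, a short uninterrupted allele.
#'
#' @param length_bp Even tract length in bp.
#' @return A [motif_decomposition()] with `tract_length()` equal to
#'   `length_bp`.
#' @export
#' @examples
#' tract_length(length_to_decomposition(138))  # 138
length_to_decomposition <- function(length_bp) {
  length_bp <- as_count(length_bp, "length_bp", 1)
  if (length_bp %% 2L != 0L) stop("tract lengths are even", call. = FALSE)
  solve_v <- function(tet) {
    v <- (length_bp - 4L * tet) / 2
    if (v == as.integer(v) && v >= 14 && v <= 26) as.integer(v) else NA_integer_
  }
  for (w in c(9L, 8L, 10L, 7L, 11L)) {
    for (x in 5:9) {
      for (z in c(7L, 4L, 5L, 6L, 8L)) {
        v <- solve_v(w + x + 3L + z)
        if (!is.na(v)) return(motif_decomposition(v, w, x, .BLOCK_T3, z))
      }
    }
  }
  for (w in c(9L, 10L, 8L, 7L, 11L)) {
    for (x in 22:55) {
      v <- solve_v(w + x)
      if (!is.na(v)) return(motif_decomposition(v, w, x))
    }
  }
  for (w in c(9L, 8L, 10L, 7L, 11L)) {
    for (x in 10:12) {
      v <- solve_v(w + x)
      if (!is.na(v)) return(motif_decomposition(v, w, x))
    }
  }
  stop(sprintf("no grammar-valid healthy-range decomposition for %d bp", length_bp),
       call. = FALSE)
}

#' Default clinical indication rates for the cohort generator
#'
#' Per-label Bernoulli probabilities used by [simulate_cohort()],
#' separately for DM2-positive individuals (taken from the reported
#' indication profile of confirmed patients) and for negatives
#' (back-solved so the cohort-wide rates match the reported request-level
#' profile at 32.8% positivity). Premutation carriers use the negative
#' rates.
#'
#' @return A list with named numeric vectors `positive` and `negative`
#'   over [indication_labels()].
#' @export
default_indication_rates <- function() {
  list(
    positive = c(myotonia = 0.35, familiarity = 0.37, asthenia = 0.18,
                 hyperCKaemia = 0.19, muscle_weakness = 0.15, myalgia = 0.15,
                 cataract = 0.11, cardiac = 0.04, endocrine = 0.04),
    negative = c(myotonia = 0.246, familiarity = 0.177, asthenia = 0.210,
                 hyperCKaemia = 0.175, muscle_weakness = 0.180, myalgia = 0.15,
                 cataract = 0.036, cardiac = 0.04, endocrine = 0.04)
  )
}

#' Simulate a diploid DM2 testing cohort
#'
#' Generates a seeded, reproducible cohort of [genotype_record()]s.
#' Individuals are DM2-positive with probability `positivity` (one normal
#' allele plus one expanded allele whose somatically mosaic repeat count
#' is a range sampled inside `expansion_range`, width `mosaic_width`
#' relative to the centre), premutation carriers with probability
#' `premutation_rate` (one normal allele plus one uninterrupted gray-zone
#' allele of 27--74 CCTG), and DM2-negative otherwise (two normal
#' alleles). Normal alleles are drawn from [build_length_spectrum()]
#' under Hardy-Weinberg sampling and instantiated as grammar-valid
#' sequences via [length_to_decomposition()]. Clinical indications are
#' sampled per label from `indication_rates`; positives get an onset age
#' drawn from Normal(49, 16.9) (a generator parameter, not an estimable
#' cohort quantity). Expanded alleles are represented by their count
#' range only and are never rendered as sequence.
#'
#' @param n Number of individuals (>= 1).
#' @param positivity Probability of a DM2-positive genotype (default
#'   0.328, the reported positivity rate).
#' @param premutation_rate Probability of a premutation carrier (default
#'   5/570, the observed carrier frequency among requests).
#' @param expansion_range Integer bounds for expanded-allele CCTG counts,
#'   within `[75, 11000]`; counts are drawn uniformly (the reported range
#'   spans 75 to over 11,000 with a mean near 5,000).
#' @param mosaic_width Relative spread of the mosaic count range (default
#'   0.05, matching reported ranges such as 51--53).
#' @param indication_rates As [default_indication_rates()].
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the arguments.
#' @param fasta Optional path: write every allele below the SR-PCR cap as
#'   FASTA (see [write_tract_fasta()]).
#' @return A list with `genotypes` (list of [genotype_record()]) and
#'   `params` (the generating parameters, seed included).
#' @export
#' @examples
#' coh <- simulate_cohort(50, seed = 7)
#' table(vapply(coh$genotypes, `[[`, "", "true_status"))
simulate_cohort <- function(n, positivity = 0.328, premutation_rate = 5 / 570,
                            expansion_range = c(75L, 11000L),
                            mosaic_width = 0.05,
                            indication_rates = default_indication_rates(),
                            seed = 1L, fasta = NULL) {
  n <- as_count(n, "n", 1)
  positivity <- as_prob(positivity, "positivity")
  premutation_rate <- as_prob(premutation_rate, "premutation_rate")
  if (positivity + premutation_rate > 1) {
    stop("positivity + premutation_rate must not exceed 1", call. = FALSE)
  }
  if (length(expansion_range) != 2L || expansion_range[1] > expansion_range[2] ||
      expansion_range[1] < 75 || expansion_range[2] > .MAX_EXPANSION) {
    stop("expansion_range must lie within [75, 11000] with lo <= hi", call. = FALSE)
  }
  mosaic_width <- as_prob(mosaic_width, "mosaic_width")
  for (side in c("positive", "negative")) {
    r <- indication_rates[[side]]
    if (is.null(r) || !all(indication_labels() %in% names(r)) ||
        any(r < 0 | r > 1)) {
      stop(sprintf("indication_rates$%s must name all indication labels with probabilities",
                   side), call. = FALSE)
    }
  }
  seed <- as_count(seed, "seed", 0)

  spectrum <- build_length_spectrum()
  lengths <- spectrum$length_bp
  probs <- spectrum$count / attr(spectrum, "total")
  decomp_by_length <- lapply(setNames(lengths, lengths), length_to_decomposition)
  registry <- dm2_registry()

  set.seed(seed)
  u <- runif(n)
  status <- ifelse(u < positivity, "DM2_positive",
                   ifelse(u < positivity + premutation_rate,
                          "premutation_carrier", "DM2_negative"))
  genotypes <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("ind%05d", i)
    normal1 <- decomp_by_length[[as.character(
      sample(lengths, 1L, prob = probs))]]
    a1 <- allele_record(paste0(id, "_a1"), decomposition = normal1)
    a2 <- switch(status[i],
      DM2_positive = {
        centre <- runif(1, expansion_range[1], expansion_range[2])
        half <- mosaic_width * centre / 2
        lo <- max(expansion_range[1], as.integer(round(centre - half)))
        hi <- min(.MAX_EXPANSION, as.integer(round(centre + half)))
        allele_record(paste0(id, "_a2"), count_range = c(lo, hi))
      },
      premutation_carrier = {
        nrep <- sample(27:74, 1L)
        allele_record(paste0(id, "_a2"),
                      decomposition = motif_decomposition(18, 9, nrep))
      },
      DM2_negative = {
        normal2 <- decomp_by_length[[as.character(
          sample(lengths, 1L, prob = probs))]]
        allele_record(paste0(id, "_a2"), decomposition = normal2)
      })
    rates <- if (status[i] == "DM2_positive") indication_rates$positive
             else indication_rates$negative
    labs <- indication_labels()
    ind <- labs[runif(length(labs)) < rates[labs]]
    onset <- if (status[i] == "DM2_positive") {
      min(90, max(12, round(rnorm(1, 49, 16.9))))
    } else NA_real_
    genotypes[[i]] <- genotype_record(
      id, a1, a2,
      sex = sample(c("M", "F"), 1L),
      year = sample(registry$year, 1L, prob = registry$cohort),
      indications = ind, onset_age = onset)
  }
  params <- list(n = n, positivity = positivity,
                 premutation_rate = premutation_rate,
                 expansion_range = expansion_range,
                 mosaic_width = mosaic_width,
                 indication_rates = indication_rates, seed = seed)
  if (!is.null(fasta)) {
    below_cap <- list()
    for (g in genotypes) {
      for (a in list(g$allele1, g$allele2)) {
        if (!is.null(a$decomposition) && effective_cctg_count(a) <= .SR_PCR_CAP) {
          below_cap[[a$id]] <- a$decomposition
        }
      }
    }
    write_tract_fasta(below_cap, fasta)
  }
  list(genotypes = genotypes, params = params)
}
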