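test_that("registry aggregation reproduces the packaged yearly table", {
  tot <- registry_totals(dm2_registry())
  expect_identical(tot$cohort, 570L)
  expect_identical(tot$males, 284L)
  expect_identical(tot$females, 286L)
  expect_identical(tot$positives, 187L)
  expect_identical(tot$positivity_rate, 32.8)
})

test_that("registry validation and additivity", {
  r <- dm2_registry()
  # single-row aggregation
  one <- registry_totals(r[r$year == 2020, ])
  expect_identical(one$positivity_rate, 23.3)  # 7/30
  # additivity over a partition of the rows
  a <- registry_totals(r[1:7, ]); b <- registry_totals(r[8:14, ])
  expect_identical(a$cohort + b$cohort, 570L)
  expect_identical(a$positives + b$positives, 187L)
  # inconsistent rows are rejected with the year named
  bad <- r; bad$males[bad$year == 2013] <- 99L
  expect_error(registry_totals(bad), "2013")
  bad <- r; bad$positives[bad$year == 2009] <- 999L
  expect_error(registry_totals(bad), "2009")
  expect_error(registry_totals(r[0, ]), "empty")
})

test_that("spectrum statistics summarise the packaged 756-chromosome spectrum", {
  s <- build_length_spectrum()
  st <- spectrum_stats(s)
  expect_identical(st$distinct_alleles, 25L)
  expect_identical(st$min_bp, 108L)
  expect_identical(st$max_bp, 168L)
  expect_identical(st$mode_bp, 138L)
  expect_identical(st$mode_pct, 21.0)
  expect_false(st$mode_tied)
  expect_true(st$unimodal)
  expect_identical(st$total, 756L)
  # the next most frequent lengths carry their printed frequencies
  freq <- setNames(st$freq$pct, st$freq$length_bp)
  expect_identical(unname(freq["134"]), 13.0)
  expect_identical(unname(freq["140"]), 11.0)
})

test_that("spectrum degenerate cases and the mode tie rule", {
  one <- frequency_spectrum(138, 10)
  st <- spectrum_stats(one)
  expect_identical(st$distinct_alleles, 1L)
  expect_identical(st$mode_bp, 138L)
  tie <- frequency_spectrum(c(120, 130), c(5, 5))
  st <- spectrum_stats(tie)
  expect_identical(st$mode_bp, 120L)  # deterministic tie-break to the smaller
  expect_true(st$mode_tied)
  expect_error(frequency_spectrum(c(121), c(3)), "even")
  expect_error(frequency_spectrum(c(120, 120), c(1, 2)), "duplicated")
})

test_that("expected heterozygosity: closed-form cases and invariances", {
  expect_identical(expected_heterozygosity(frequency_spectrum(c(110, 112), c(7, 7))), 0.5)
  expect_identical(expected_heterozygosity(frequency_spectrum(138, 5)), 0)
  # invariant under relabeling of allele lengths
  s1 <- frequency_spectrum(c(110, 120, 130), c(2, 3, 5))
  s2 <- frequency_spectrum(c(150, 108, 166), c(2, 3, 5))
  expect_equal(expected_heterozygosity(s1), expected_heterozygosity(s2))
  # maximal for the uniform spectrum at fixed k
  for (k in 2:6) {
    unif <- frequency_spectrum(seq(110, by = 2, length.out = k), rep(10, k))
    set.seed(40 + k)
    skew <- frequency_spectrum(seq(110, by = 2, length.out = k),
                               sample(1:20, k, replace = TRUE) + c(30, rep(0, k - 1)))
    expect_gte(expected_heterozygosity(unif) + 1e-12, expected_heterozygosity(skew))
  }
})

test_that("observed heterozygosity matches HWE expectation on a sampled cohort", {
  s <- build_length_spectrum()
  h_exp <- expected_heterozygosity(s)
  coh <- simulate_cohort(5000, positivity = 0, premutation_rate = 0, seed = 41)
  h_obs <- observed_heterozygosity(coh$genotypes)
  se <- sqrt(h_exp * (1 - h_exp) / 5000)
  expect_lt(abs(h_obs - h_exp), 3 * se)
  # degenerate cases
  d <- motif_decomposition(21, 9, 5, c("TCTG", "CCTG", "TCTG"), 7)
  hom <- genotype_record("h", allele_record("1", d), allele_record("2", d))
  expect_identical(observed_heterozygosity(list(hom)), 0)
  het <- genotype_record("h", allele_record("1", d),
                         allele_record("2", motif_decomposition(18, 10, 23)))
  expect_identical(observed_heterozygosity(list(het)), 1)
})

test_that("motif accounting on the catalogue reproduces the printed shares", {
  mf <- motif_frequencies(build_sequenced_catalogue())
  expect_identical(mf$denominators$all, 103L)
  expect_identical(mf$denominators$interrupted, 98L)
  core <- setNames(mf$core$pct, mf$core$core)
  expect_identical(unname(core["(CCTG)5(NCTG)3(CCTG)7"]), 62.1)
  expect_identical(unname(core["(CCTG)6(NCTG)3(CCTG)7"]), 20.4)
  win <- setNames(mf$interruption$pct, mf$interruption$window)
  expect_identical(unname(win["y=3"]), 92.9)
  expect_identical(unname(win["y=5"]), 7.1)
  full <- setNames(mf$full_motif$pct, mf$full_motif$motif)
  expect_identical(unname(full["(TG)21(TCTG)9(CCTG)5(NCTG)3(CCTG)7"]), 8.7)
  expect_identical(unname(full["(TG)17(TCTG)9(CCTG)5(NCTG)3(CCTG)7"]), 8.7)
  # single-allele degenerate case
  one <- motif_frequencies(list(motif_decomposition(16, 7, 5, c("TCTG", "CCTG", "TCTG"), 4)))
  expect_identical(one$core$pct, 100.0)
  expect_error(motif_frequencies(list()), "no alleles")
})

test_that("exclusive frequency tables sum to ~100 and are nonnegative", {
  mf <- motif_frequencies(build_sequenced_catalogue())
  for (df in list(mf$core, mf$interruption, mf$full_motif)) {
    expect_true(all(df$pct >= 0))
    # half-up rounding moves each entry by at most 0.05
    expect_lte(abs(sum(df$pct) - 100), 0.05 * nrow(df) + 1e-9)
  }
  tal <- classify_cohort(lapply(build_sequenced_catalogue(), function(d) {
    allele_record("a", decomposition = d)
  }))
  expect_lt(abs(sum(tal$structural$pct) - 100), 0.5)
})

test_that("indication profiles tabulate positives and the whole cohort", {
  d <- motif_decomposition(21, 9, 5, c("TCTG", "CCTG", "TCTG"), 7)
  mk <- function(id, status_allele, ind) {
    genotype_record(id, allele_record("1", d), status_allele, indications = ind)
  }
  pos <- mk("p1", allele_record("2", count_range = 2000), c("myotonia"))
  pos2 <- mk("p2", allele_record("2b", count_range = 5000), c("myotonia", "cataract"))
  neg <- mk("n1", allele_record("3", d), c("asthenia"))
  prof <- indication_profile(list(pos, pos2, neg))
  expect_identical(prof$pct_positives[prof$label == "myotonia"], 100.0)
  expect_identical(prof$pct_positives[prof$label == "cataract"], 50.0)
  expect_identical(prof$pct_all[prof$label == "asthenia"], 33.3)
  expect_identical(attr(prof, "n_positives"), 2L)
  expect_warning(indication_profile(list(neg)), "no DM2-positive")
})
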