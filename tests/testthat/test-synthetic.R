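test_that("the sequenced catalogue has the reported composition", {
  cat_ <- build_sequenced_catalogue()
  expect_length(cat_, 103L)
  ys <- vapply(cat_, interruption_count, 0L)
  expect_identical(sum(ys > 0L), 98L)
  expect_identical(sum(ys == 3L), 91L)
  expect_identical(sum(ys == 5L), 7L)
  expect_identical(sum(ys == 0L), 5L)
  # the printed extreme structures are present verbatim
  notations <- vapply(cat_, repeat_notation, "")
  expect_true("(TG)16(TCTG)7(CCTG)5(NCTG)3(CCTG)4" %in% notations)  # 108 bp
  expect_true("(TG)18(TCTG)10(CCTG)23" %in% notations)              # 168 bp
  expect_identical(sum(notations == "(TG)21(TCTG)9(CCTG)5(NCTG)3(CCTG)7"), 9L)
  expect_identical(sum(notations == "(TG)17(TCTG)9(CCTG)5(NCTG)3(CCTG)7"), 9L)
  # the two rare short uninterrupted alleles
  xs <- vapply(cat_, function(d) d$x, 0L)
  expect_true(all(c(10L, 12L) %in% xs[ys == 0L]))
  # flanks inside the observed polymorphic ranges
  vs <- vapply(cat_, function(d) d$v, 0L)
  ws <- vapply(cat_, function(d) d$w, 0L)
  expect_true(all(vs >= 14 & vs <= 26))
  expect_true(all(ws >= 7 & ws <= 11))
  lens <- vapply(cat_, tract_length, 0L)
  expect_true(all(lens >= 108 & lens <= 168))
})

test_that("the catalogue is deterministic and round-trips through the grammar", {
  c1 <- build_sequenced_catalogue()
  c2 <- build_sequenced_catalogue()
  expect_identical(c1, c2)
  for (d in c1) {
    expect_true(same_decomposition(decompose_tract(render_tract(d))$decomposition, d))
  }
})

test_that("the packaged length spectrum carries the printed frequencies", {
  s <- build_length_spectrum()
  expect_identical(attr(s, "total"), 756L)
  expect_identical(nrow(s), 25L)
  cnt <- setNames(s$count, s$length_bp)
  expect_identical(unname(cnt["138"]), 159L)  # 21% of 756
  expect_identical(unname(cnt["134"]), 98L)
  expect_identical(unname(cnt["140"]), 83L)
  expect_identical(unname(cnt["136"]), 76L)
  expect_identical(unname(cnt["142"]), 53L)
  expect_true(all(s$count >= 1L))
  expect_identical(build_length_spectrum(), s)  # deterministic
})

test_that("every spectrum length instantiates as a healthy-range tract of that size", {
  s <- build_length_spectrum()
  for (L in s$length_bp) {
    d <- length_to_decomposition(L)
    expect_identical(tract_length(d), L)
    expect_true(structural_class(d) != "expanded")
    expect_identical(diagnostic_category(d), "normal")
    expect_true(same_decomposition(decompose_tract(render_tract(d))$decomposition, d))
  }
  expect_error(length_to_decomposition(109), "even")
})

test_that("simulate_cohort is seed-reproducible and honours its spec", {
  c1 <- simulate_cohort(120, seed = 51)
  c2 <- simulate_cohort(120, seed = 51)
  expect_identical(genotypes_to_table(c1$genotypes), genotypes_to_table(c2$genotypes))
  c3 <- simulate_cohort(120, seed = 52)
  expect_false(identical(genotypes_to_table(c1$genotypes),
                         genotypes_to_table(c3$genotypes)))
  for (g in c1$genotypes) {
    cats <- c(g$allele1$diagnostic_category, g$allele2$diagnostic_category)
    expect_identical(g$true_status,
                     if (any(cats == "pathogenic")) "DM2_positive"
                     else if (any(cats == "gray_premutation")) "premutation_carrier"
                     else "DM2_negative")
    if (g$true_status == "DM2_positive") {
      cr <- g$allele2$count_range
      expect_true(cr[1] >= 75 && cr[2] <= 11000 && cr[1] <= cr[2])
    }
  }
  expect_error(simulate_cohort(0), "'n'")
  expect_error(simulate_cohort(10, positivity = 1.2), "probability")
  expect_error(simulate_cohort(10, positivity = 0.7, premutation_rate = 0.5),
               "must not exceed 1")
  expect_error(simulate_cohort(10, expansion_range = c(10, 50)), "75")
})

test_that("simulated positivity converges to the generating rate", {
  coh <- simulate_cohort(4000, positivity = 0.328, seed = 53)
  frac <- mean(vapply(coh$genotypes, `[[`, "", "true_status") == "DM2_positive")
  se <- sqrt(0.328 * 0.672 / 4000)
  expect_lt(abs(frac - 0.328), 3 * se)
})

test_that("generated normal alleles decompose back to their drawn spectrum length", {
  coh <- simulate_cohort(150, seed = 54)
  s <- build_length_spectrum()
  for (g in coh$genotypes) {
    for (a in list(g$allele1, g$allele2)) {
      if (!is.null(a$decomposition) && a$diagnostic_category == "normal") {
        L <- tract_length(a$decomposition)
        expect_true(L %in% s$length_bp)
        got <- decompose_tract(render_tract(a$decomposition))$decomposition
        expect_identical(tract_length(got), L)
      }
    }
  }
})
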