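test_that("worked healthy-range structures render to their reported lengths", {
  cases <- list(
    list(d = motif_decomposition(18, 10, 23), bp = 168),
    list(d = motif_decomposition(16, 7, 5, c("TCTG", "CCTG", "TCTG"), 4), bp = 108),
    list(d = motif_decomposition(21, 9, 5, c("TCTG", "CCTG", "TCTG"), 7), bp = 138),
    list(d = motif_decomposition(17, 9, 5, c("TCTG", "CCTG", "TCTG"), 7), bp = 130)
  )
  for (cs in cases) {
    expect_identical(tract_length(cs$d), as.integer(cs$bp))
    expect_identical(nchar(render_tract(cs$d)), as.integer(cs$bp))
  }
  s168 <- render_tract(cases[[1]]$d)
  expect_match(s168, "^TGTG")
  expect_match(s168, "CCTG$")
})

test_that("degenerate and empty decompositions behave", {
  d0 <- motif_decomposition(0, 0, 0)
  expect_identical(render_tract(d0), "")
  expect_identical(tract_length(d0), 0L)
  expect_identical(repeat_notation(d0), "(TG)0(TCTG)0(CCTG)0")
  expect_warning(motif_decomposition(0, 9, 5), "polymorphic range")
  expect_warning(motif_decomposition(18, 0, 5), "polymorphic range")
})

test_that("constructor rejects grammar-invalid decompositions by rule", {
  expect_error(motif_decomposition(1, 1, 1, c("CCTG", "TCTG"), 0),
               "must not start or end with CCTG")
  expect_error(motif_decomposition(1, 1, 1, c("TCTG", "CCTG"), 0),
               "must not start or end with CCTG")
  expect_error(motif_decomposition(1, 1, 0, c("TCTG"), 0), "x >= 1")
  expect_error(motif_decomposition(1, 1, 3, character(), 2), "y = 0 implies z = 0")
  expect_error(motif_decomposition(1, 1, 1, c("TTTG"), 0), "invalid block label")
  expect_error(motif_decomposition(-1, 0, 1), "'v'")
})

test_that("CCTG run and total accounting match direct tetramer counts", {
  b3 <- c("TCTG", "CCTG", "TCTG")
  b5 <- c("TCTG", "CCTG", "TCTG", "CCTG", "TCTG")
  d1 <- motif_decomposition(20, 9, 5, b3, 7)
  expect_identical(longest_cctg_run(d1), 7L)
  expect_identical(total_cctg(d1), 13L)
  d2 <- motif_decomposition(18, 10, 23)
  expect_identical(longest_cctg_run(d2), 23L)
  expect_identical(total_cctg(d2), 23L)
  d3 <- motif_decomposition(20, 9, 6, b5, 6)
  expect_identical(longest_cctg_run(d3), 6L)   # runs are 6, 1, 1, 6
  expect_identical(total_cctg(d3), 14L)
})

test_that("canonical notation follows the field's convention", {
  expect_identical(
    repeat_notation(motif_decomposition(16, 7, 5, c("TCTG", "CCTG", "TCTG"), 4)),
    "(TG)16(TCTG)7(CCTG)5(NCTG)3(CCTG)4")
  expect_identical(repeat_notation(motif_decomposition(18, 10, 23)),
                   "(TG)18(TCTG)10(CCTG)23")
  expect_identical(core_notation(motif_decomposition(18, 10, 23)), "(CCTG)23")
})

test_that("decompose parses the worked structures and the 12-mer example", {
  d108 <- motif_decomposition(16, 7, 5, c("TCTG", "CCTG", "TCTG"), 4)
  got <- decompose_tract(render_tract(d108))
  expect_true(same_decomposition(got$decomposition, d108))
  expect_identical(got$start, 0L)
  expect_identical(got$end, 108L)
  expect_identical(got$strand, "+")

  d168 <- motif_decomposition(18, 10, 23)
  got <- decompose_tract(render_tract(d168))$decomposition
  expect_true(same_decomposition(got, d168))
  expect_identical(interruption_count(got), 0L)
  expect_identical(got$z, 0L)

  got <- decompose_tract("TGTGTCTGCCTG")$decomposition
  expect_true(same_decomposition(got, suppressWarnings(motif_decomposition(2, 1, 1))))
  # the brute-force oracle agrees this segmentation is the only one
  all_segs <- enumerate_decompositions("TGTGTCTGCCTG")
  expect_length(all_segs, 1L)
  expect_true(same_decomposition(all_segs[[1]], got))
})

test_that("reverse-complement input is located and the strand recorded", {
  d <- motif_decomposition(21, 9, 5, c("TCTG", "CCTG", "TCTG"), 7)
  fwd <- render_tract(d)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  got <- decompose_tract(rc)
  expect_identical(got$strand, "-")
  expect_true(same_decomposition(got$decomposition, d))
})

test_that("parse errors carry the offending tetramer or offset", {
  expect_error(decompose_tract("TGTGAAAA"), "cannot decompose")
  # a non-grammar tetramer inside an otherwise in-frame tract
  expect_error(decompose_tract("TCTGCCTGTTTGCCTG"), "cannot decompose")
  expect_error(decompose_tract("NNNN"), "A/C/G/T")
  expect_error(decompose_tract(c("CCTG", "CCTG")), "single character")
})

test_that("tract location inside flanking context works with full = FALSE", {
  d <- motif_decomposition(16, 7, 5, c("TCTG", "CCTG", "TCTG"), 4)
  seq <- paste0("GGCCTTATAACCAA", render_tract(d), "AATTAGGGGAC")
  expect_error(decompose_tract(seq), "full = FALSE")
  got <- decompose_tract(seq, full = FALSE)
  expect_true(same_decomposition(got$decomposition, d))
  expect_identical(got$start, 14L)
  expect_identical(got$end, 14L + 108L)
})

test_that("render/decompose round trip holds across random valid tracts", {
  set.seed(11)
  for (i in 1:300) {
    d <- random_decomposition()
    got <- decompose_tract(render_tract(d))$decomposition
    expect_true(same_decomposition(got, d))
    expect_identical(tract_length(d), nchar(render_tract(d)))
  }
})

test_that("greedy parse agrees with exhaustive segmentation on small tracts", {
  set.seed(12)
  for (i in 1:60) {
    d <- random_small_decomposition(80L)
    seq <- render_tract(d)
    segs <- enumerate_decompositions(seq)
    expect_length(segs, 1L)
    expect_true(same_decomposition(segs[[1]],
                                   decompose_tract(seq)$decomposition))
  }
})

test_that("a single inserted base can never be silently re-framed", {
  set.seed(13)
  for (i in 1:40) {
    d <- random_small_decomposition(80L)
    seq <- render_tract(d)
    pos <- sample(0:nchar(seq), 1L)
    base <- sample(c("A", "C", "G", "T"), 1L)
    corrupted <- paste0(substr(seq, 1, pos), base,
                        substr(seq, pos + 1L, nchar(seq)))
    expect_error(decompose_tract(corrupted))
  }
})
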