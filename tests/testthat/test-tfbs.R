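test_that("upstream extraction follows the coordinate conventions", {
  set.seed(5)
  chr <- random_dna(8000)
  genome <- c(chr1 = chr)
  genes <- data.frame(
    id = c("plus", "minus", "short"),
    contig = "chr1",
    start = c(5001, 5000, 1500),
    strand = c("+", "-", "+"))
  ps <- extract_upstream(genes, genome, window = 2000)
  expect_equal(ps$seqs[["plus"]], substr(chr, 3001, 5000))
  expect_equal(ps$seqs[["minus"]], revcomp_oracle(substr(chr, 5001, 7000)))
  expect_equal(ps$seqs[["short"]], substr(chr, 1, 1499))
  expect_true(ps$truncated[["short"]])
  expect_false(ps$truncated[["plus"]])

  bad <- data.frame(id = c("x", "y"), contig = c("nope", "chr1"),
                    start = c(10, 9000), strand = "+")
  ps2 <- extract_upstream(bad, genome)
  err <- attr(ps2, "errors")
  expect_equal(sort(err$id), c("x", "y"))
  expect_equal(length(ps2$seqs), 0)
})

test_that("scanning counts overlapping IUPAC matches with 1-based positions", {
  ps <- promoter_set(c(g1 = "TTGCATGCA"), window = 9)
  sc <- scan_promoters(ps, motif_pattern("m", "TGCA"), strands = "plus")
  expect_equal(attr(sc, "positions")$g1$plus, c(2L, 6L))
  expect_equal(sc$plus, 2)

  ps2 <- promoter_set(c(g1 = "AAA"), window = 3)
  expect_equal(scan_promoters(ps2, "AA", strands = "plus")$plus, 2)

  ps3 <- promoter_set(c(g1 = "TGCACTC"), window = 7)
  expect_equal(scan_promoters(ps3, "TGCRCNC", strands = "plus")$plus, 1)

  # N in the subject never matches, not even pattern N
  ps4 <- promoter_set(c(g1 = "ANGT"), window = 4)
  expect_equal(scan_promoters(ps4, "N", strands = "plus")$plus, 3)
  expect_equal(scan_promoters(ps4, "ANG", strands = "plus")$plus, 0)
})

test_that("scanner equals the naive expand-and-slide oracle", {
  set.seed(101)
  codes <- names(iupac_sets_oracle)
  for (i in 1:150) {
    seq <- random_dna(sample(20:200, 1),
                      alphabet = c("A", "C", "G", "T", "N"))
    motif <- paste(sample(codes, sample(2:10, 1), replace = TRUE),
                   collapse = "")
    ps <- promoter_set(setNames(seq, "g"), window = nchar(seq))
    sc <- scan_promoters(ps, motif)
    pos <- attr(sc, "positions")$g
    expect_identical(pos$plus, naive_scan_oracle(seq, motif))
    expect_identical(pos$minus, naive_scan_oracle(seq, revcomp_oracle(motif)))
  }
})

test_that("plus-strand scan is symmetric under reverse complementation", {
  set.seed(55)
  for (i in 1:25) {
    seq <- random_dna(100)
    motif <- paste(sample(names(iupac_sets_oracle), 6, replace = TRUE),
                   collapse = "")
    a <- scan_promoters(promoter_set(c(g = seq), 100), motif,
                        strands = "plus")$plus
    b <- scan_promoters(promoter_set(c(g = revcomp_oracle(seq)), 100),
                        revcomp_oracle(motif), strands = "plus")$plus
    expect_equal(a, b)
  }
})

test_that("two-proportion z matches hand evaluation and chi-square", {
  zt <- two_proportion_z(3, 26, 3, 198)
  expect_equal(zt$z, 2.98, tolerance = 0.01)
  expect_lt(abs(zt$p - 0.003), 2e-4)

  expect_equal(two_proportion_z(5, 50, 10, 100)$z, 0)
  expect_equal(two_proportion_z(5, 50, 10, 100)$p, 1)
  expect_equal(two_proportion_z(26, 26, 198, 198)$p, 1) # degenerate pbar = 1
  expect_equal(two_proportion_z(0, 26, 0, 198)$p, 1)    # degenerate pbar = 0

  # z^2 equals the Pearson chi-square without continuity correction
  set.seed(3)
  for (i in 1:30) {
    n1 <- sample(10:60, 1); n2 <- sample(50:300, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    zt <- two_proportion_z(x1, n1, x2, n2)
    chi <- suppressWarnings(chisq.test(
      matrix(c(x1, n1 - x1, x2, n2 - x2), 2), correct = FALSE))
    expect_equal(zt$z^2, unname(chi$statistic), tolerance = 1e-10)
  }
})

test_that("cohort comparison tests presence, not site counts", {
  fg <- promoter_set(c(a = "TGCATGCA", b = "GGGGGGGG", c = "TGCAAAAA"), 8)
  bg <- promoter_set(c(d = "CCCCCCCC", e = "TGCACCCC"), 8)
  comp <- compare_tfbs_frequency(scan_promoters(fg, motif_pattern("m", "TGCA")),
                                 scan_promoters(bg, motif_pattern("m", "TGCA")))
  expect_equal(comp$x1, 2) # gene a has 2 sites but counts once
  expect_equal(comp$n1, 3)
  expect_equal(comp$x2, 1)
  expect_equal(comp$pct_fg, 200 / 3, tolerance = 1e-10)
  expect_equal(comp$motif, "m")
})

test_that("control cohort selection is seeded and validated", {
  genes <- sprintf("g%03d", 1:250)
  reg <- genes[1:40]
  a <- select_control_cohort(genes, reg, size = 198, seed = 4)
  b <- select_control_cohort(genes, reg, size = 198, seed = 4)
  expect_identical(a, b)
  expect_equal(length(a), 198)
  expect_false(any(a %in% reg))
  # pool exactly equal to size -> the whole pool
  expect_setequal(select_control_cohort(genes[1:200], genes[1:2], 198),
                  genes[3:200])
  expect_equal(select_control_cohort(genes, reg, size = 0), character(0))
  expect_error(select_control_cohort(genes[1:100], reg, 198), "available")
})
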