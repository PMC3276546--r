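test_that("panel round-trips through delimited text", {
  panel <- toy_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_freq_panel(panel, path)
  back <- read_freq_panel(path)
  expect_equal(back$freq, panel$freq)
  expect_equal(back$sizes, panel$sizes)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_freq_panel(panel, tsv)
  expect_equal(read_freq_panel(tsv)$freq, panel$freq)
})

test_that("load-time renormalization tolerates rounded tables but not junk", {
  rounded <- tibble::tibble(
    population = "p", locus = "L1", allele = c("a", "b"),
    frequency = c(0.598, 0.399), sample_size = 50
  )
  panel <- freq_panel(rounded)
  expect_equal(sum(panel$freq$frequency), 1, tolerance = 1e-12)
  expect_equal(panel$freq$frequency, c(0.598, 0.399) / 0.997)

  bad <- rounded
  bad$frequency <- c(0.6, 0.6)
  expect_error(freq_panel(bad), class = "famlr_validation_error")
  neg <- rounded
  neg$frequency <- c(1.2, -0.2)
  expect_error(freq_panel(neg), class = "famlr_validation_error")
  expect_error(
    freq_panel(rounded[, setdiff(names(rounded), "allele")]),
    class = "famlr_format_error"
  )
})

test_that("allele universe is completed with zero frequencies", {
  freq <- tibble::tibble(
    population = c("A", "A", "B"),
    locus = "L1",
    allele = c("x", "y", "x"),
    frequency = c(0.3, 0.7, 1),
    sample_size = c(10, 10, 20)
  )
  panel <- freq_panel(freq)
  pb <- locus_freq(panel, "B", "L1")
  expect_equal(pb, c(x = 1, y = 0))
  expect_error(locus_freq(panel, "C", "L1"), class = "famlr_validation_error")
})

test_that("gene diversity matches analytic values and supports correction", {
  mono <- one_locus_panel(c(a = 1))
  expect_equal(gene_diversity(mono)$h, 0)

  equi <- generate_equifrequent_panel(3, 10, n = 200)
  expect_equal(gene_diversity(equi)$h, rep(0.9, 3))

  # 2n/(2n-1) switch
  pan <- one_locus_panel(c(a = 0.6, b = 0.4), n = 50)
  expect_equal(
    gene_diversity(pan, corrected = TRUE)$h,
    (1 - 0.6^2 - 0.4^2) * 100 / 99
  )
  expect_error(gene_diversity(pan, populations = "zz"),
    class = "famlr_validation_error"
  )
})

test_that("profile entropy matches analytic values", {
  expect_equal(profile_entropy(one_locus_panel(c(a = 0.5, b = 0.5)))$bits, 1)
  expect_equal(profile_entropy(one_locus_panel(c(a = 1)))$bits, 0)
  equi <- generate_equifrequent_panel(13, 10, n = 200)
  s <- panel_diversity(equi)
  expect_equal(s$entropy_haploid_bits, 13 * log2(10), tolerance = 1e-12)
  expect_equal(s$entropy_diploid_bits, 2 * 13 * log2(10), tolerance = 1e-12)
})

test_that("diversity and entropy ignore allele relabeling and zero alleles", {
  p <- c(u = 0.2, v = 0.5, w = 0.3)
  a <- one_locus_panel(p)
  b <- one_locus_panel(setNames(p, c("z9", "z1", "z5")))
  with_zero <- one_locus_panel(c(p, ghost = 0))
  expect_equal(gene_diversity(a)$h, gene_diversity(b)$h)
  expect_equal(gene_diversity(a)$h, gene_diversity(with_zero)$h)
  expect_equal(profile_entropy(a)$bits, profile_entropy(with_zero)$bits)
  expect_true(profile_entropy(a)$bits >= 0)
})

test_that("Weir-Cockerham FST matches the definitional components", {
  panel <- two_pop_biallelic(0.2, 0.8, n = 100)
  got <- fst_wc(panel, "A", "B")
  expect_equal(got$fst_raw, wc_biallelic_oracle(0.2, 0.8, 100, 100),
    tolerance = 1e-12
  )
  # a second configuration with unequal sizes
  panel2 <- freq_panel(tibble::tibble(
    population = rep(c("A", "B"), each = 2), locus = "L1",
    allele = rep(c("x", "y"), 2), frequency = c(0.35, 0.65, 0.5, 0.5),
    sample_size = rep(c(80, 150), each = 2)
  ))
  expect_equal(fst_wc(panel2, "A", "B")$fst_raw,
    wc_biallelic_oracle(0.35, 0.5, 80, 150),
    tolerance = 1e-12
  )
})

test_that("FST is symmetric, truncated at zero, and flags degeneracy", {
  panel <- two_pop_biallelic(0.3, 0.3, n = 50)
  same <- fst_wc(panel, "A", "B")
  expect_lte(same$fst_raw, 0)
  expect_equal(same$fst, 0)

  panel2 <- two_pop_biallelic(0.2, 0.7, n = 60)
  expect_equal(
    fst_wc(panel2, "A", "B")$fst_raw,
    fst_wc(panel2, "B", "A")$fst_raw
  )
  expect_error(fst_wc(panel2, "A", "nope"), class = "famlr_validation_error")

  mono <- freq_panel(tibble::tibble(
    population = c("A", "B"), locus = "L1", allele = "x",
    frequency = 1, sample_size = 10
  ))
  deg <- fst_wc(mono, "A", "B")
  expect_false(deg$estimable)
  expect_true(is.na(deg$fst))
})

test_that("raw FST grows with allele-frequency divergence", {
  raw <- vapply(
    c(0.55, 0.65, 0.8, 0.95),
    function(p2) fst_wc(two_pop_biallelic(0.5, p2, n = 5000), "A", "B")$fst_raw,
    0
  )
  expect_true(all(diff(raw) > 0))
})

test_that("fst_matrix covers every unordered pair", {
  panel <- codis_like_fixture()
  m <- fst_matrix(panel)
  expect_equal(nrow(m), choose(5, 2))
  expect_true(all(m$estimable))
  expect_true(all(m$fst >= 0))
})
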