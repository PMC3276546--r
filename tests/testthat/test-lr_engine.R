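test_that("frequency flooring honours its contract", {
  p <- c(a = 0.2, b = 0.8)
  out <- floor_frequencies(p, "a", floor = 0.001)
  expect_equal(out, p, ignore_attr = TRUE)
  expect_equal(attr(out, "n_floored"), 0)

  p0 <- c(a = 0, b = 1)
  out0 <- floor_frequencies(p0, "a", floor = 0.001)
  expect_equal(unname(out0), c(0.001, 0.999), ignore_attr = TRUE)
  expect_equal(attr(out0, "n_floored"), 1)

  p2 <- c(a = 0, b = 0, c = 1)
  out2 <- floor_frequencies(p2, c("a", "b"), floor = 0.001)
  expect_equal(unname(out2), c(0.001, 0.001, 0.998), ignore_attr = TRUE)
  expect_equal(sum(out2), 1)

  expect_error(floor_frequencies(p, "a", floor = 0.6),
    class = "famlr_config_error"
  )
  expect_error(floor_frequencies(c(a = 0.5, b = 0.5), "a", floor = 0.5),
    class = "famlr_config_error"
  )
})

test_that("locus LR matches classical paternity/sibling algebra", {
  p <- c(a = 0.1, b = 0.5, c = 0.4)
  # unrelated numerator == denominator for any pair
  set.seed(1)
  for (i in 1:10) {
    g1 <- sample(names(p), 2, TRUE)
    g2 <- sample(names(p), 2, TRUE)
    expect_equal(locus_lr(g1, g2, "unrelated", p, theta_assumed = 0.05), 1)
  }
  expect_equal(
    locus_lr(c("a", "b"), c("a", "c"), "parent-offspring", p, 0),
    po_lr_shared(0.1)
  )
  expect_equal(
    locus_lr(c("a", "a"), c("a", "a"), "sibling", p, 0),
    sib_lr_homhom(0.1)
  )
  # parent-offspring exclusion: no shared allele -> LR 0
  expect_equal(locus_lr(c("a", "a"), c("b", "c"), "parent-offspring", p, 0), 0)
})

test_that("profile log LR adds over loci and propagates -Inf", {
  panel <- freq_panel(tibble::tibble(
    population = "p1",
    locus = rep(c("L1", "L2"), each = 3),
    allele = rep(c("a", "b", "c"), 2),
    frequency = rep(c(0.1, 0.5, 0.4), 2),
    sample_size = 1000
  ))
  pairs <- tibble::tibble(
    pair_id = 1L, locus = c("L1", "L2"),
    a1_1 = c("a", "a"), a1_2 = c("b", "a"),
    a2_1 = c("a", "a"), a2_2 = c("c", "a")
  )
  # L1: (ab, ac) PO -> 2.5 ; L2: (aa, aa) PO -> 1/p = 10
  res <- profile_loglr(pairs, panel, "p1", "parent-offspring",
    theta_assumed = 0
  )
  expect_equal(res$loglr, log(2.5) + log(10), tolerance = 1e-12)
  expect_false(res$degenerate)

  sib <- profile_loglr(pairs, panel, "p1", "sibling", theta_assumed = 0)
  expect_equal(sib$loglr, log(2.5 / 2 + 1 / 4) + log(sib_lr_homhom(0.1)),
    tolerance = 1e-10
  )

  # no shared allele at L2 -> parent-offspring LR 0 there, profile -Inf
  excl <- tibble::tibble(
    pair_id = 1L, locus = c("L1", "L2"),
    a1_1 = c("a", "a"), a1_2 = c("b", "a"),
    a2_1 = c("a", "b"), a2_2 = c("c", "c")
  )
  res2 <- profile_loglr(excl, panel, "p1", "parent-offspring",
    theta_assumed = 0
  )
  expect_identical(res2$loglr, -Inf)
  expect_true(res2$degenerate)

  expect_error(
    profile_loglr(dplyr::mutate(pairs, locus = c("L1", "LX")), panel, "p1", "sibling"),
    class = "famlr_validation_error"
  )
})

test_that("confidence intervals are symmetric in log space at the stated z", {
  panel <- generate_equifrequent_panel(5, 8, n = 200)
  pr <- simulate_pairs(panel, "pop1", "sibling", 20, seed = 4)
  ci <- lr_confint(pr, panel, "pop1", "sibling", alpha = 0.05)
  fin <- ci[!ci$degenerate, ]
  expect_true(all(fin$variance >= 0))
  expect_equal(fin$z, rep(qnorm(0.975), nrow(fin)))
  expect_equal(fin$lcl, fin$loglr - fin$z * sqrt(fin$variance))
  expect_equal(fin$ucl - fin$loglr, fin$loglr - fin$lcl, tolerance = 1e-9)
  expect_true(all(fin$lcl <= fin$loglr & fin$loglr <= fin$ucl))

  one <- lr_confint(pr, panel, "pop1", "sibling", alpha = 0.05, one_sided = TRUE)
  expect_equal(one$z, rep(qnorm(0.95), nrow(one)))
  expect_true(all(is.infinite(one$ucl[!one$degenerate])))

  expect_error(lr_confint(pr, panel, "pop1", "sibling", alpha = 1.2),
    class = "famlr_config_error"
  )
})

test_that("unrelated hypothesis gives zero log LR with zero variance", {
  panel <- generate_equifrequent_panel(4, 6, n = 100)
  pr <- simulate_pairs(panel, "pop1", "unrelated", 10, seed = 2)
  ci <- lr_confint(pr, panel, "pop1", "unrelated")
  expect_equal(ci$loglr, rep(0, 10), tolerance = 1e-8)
  expect_equal(ci$variance, rep(0, 10), tolerance = 1e-8)
  expect_equal(ci$lcl, ci$ucl, tolerance = 1e-7)
})

test_that("degenerate -Inf pairs produce flagged (-Inf, -Inf) intervals", {
  panel <- generate_equifrequent_panel(3, 10, n = 200)
  unr <- simulate_pairs(panel, "pop1", "unrelated", 200, seed = 5)
  ci <- lr_confint(unr, panel, "pop1", "parent-offspring")
  bad <- ci[ci$degenerate, ]
  expect_gt(nrow(bad), 0) # unrelated pairs rarely share an allele everywhere
  expect_true(all(bad$loglr == -Inf))
  expect_true(all(bad$lcl == -Inf & bad$ucl == -Inf))
  expect_true(all(is.na(bad$variance)))
})

test_that("CI width grows with theta_ci and shrinks with sample size", {
  panel_small <- generate_equifrequent_panel(6, 10, n = 50)
  panel_big <- generate_equifrequent_panel(6, 10, n = 5000)
  pr <- simulate_pairs(panel_small, "pop1", "sibling", 10, seed = 6)

  widths <- function(panel, tci) {
    ci <- lr_confint(pr, panel, "pop1", "sibling",
      theta_assumed = 0.01, theta_ci = tci, freq_floor = 1e-4
    )
    ci$ucl - ci$lcl
  }
  w0 <- widths(panel_small, 0.001)
  w1 <- widths(panel_small, 0.01)
  w2 <- widths(panel_small, 0.05)
  expect_true(all(w1 >= w0) && all(w2 >= w1))
  expect_true(all(widths(panel_big, 0.01) <= w1))
})

test_that("cross-population evaluation floors unseen alleles and counts it", {
  pan <- freq_panel(tibble::tibble(
    population = rep(c("A", "B"), each = 2),
    locus = "L1",
    allele = c("a", "b", "b", "c"),
    frequency = c(0.5, 0.5, 0.4, 0.6),
    sample_size = 100
  ))
  pairs <- tibble::tibble(
    pair_id = 1L, locus = "L1",
    a1_1 = "a", a1_2 = "a", a2_1 = "a", a2_2 = "b"
  )
  res <- lr_confint(pairs, pan, "B", "sibling")
  expect_false(res$degenerate)
  expect_gt(res$n_floored, 0)
  expect_true(is.finite(res$loglr))
})
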