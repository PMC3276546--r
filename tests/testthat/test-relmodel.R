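test_that("IBD coefficients and kinship match pedigree theory", {
  expect_equal(unname(ibd_coefficients("unrelated")), c(1, 0, 0))
  expect_equal(unname(ibd_coefficients("parent-offspring")), c(0, 1, 0))
  expect_equal(unname(ibd_coefficients("sibling")), c(0.25, 0.5, 0.25))
  expect_equal(unname(ibd_coefficients("half-sibling")), c(0.5, 0.5, 0))
  expect_equal(unname(ibd_coefficients("first-cousin")), c(0.75, 0.25, 0))
  expect_equal(unname(ibd_coefficients("second-cousin")), c(15 / 16, 1 / 16, 0))

  # tolerant name matching
  expect_equal(
    ibd_coefficients("Parent Offspring"),
    ibd_coefficients("parent-offspring")
  )
  expect_equal(ibd_coefficients("siblings"), ibd_coefficients("sibling"))
  expect_error(ibd_coefficients("twin"), class = "famlr_validation_error")

  expect_equal(kinship("sibling"), 0.25)
  expect_equal(kinship("second-cousin"), 0.015625)
  expect_equal(kinship("unrelated"), 0)
  expect_equal(relationships()$kinship,
    c(0.25, 0.25, 0.125, 0.0625, 0.015625, 0),
    ignore_attr = TRUE
  )
})

test_that("urn rule gives the stated next-draw probabilities", {
  p <- c(a = 0.1, b = 0.9)
  expect_equal(urn_next_prob(c(0, 0), p, theta = 0.03), p)
  nxt <- urn_next_prob(c(1, 0), p, theta = 0.03)
  expect_equal(unname(nxt["a"]), 0.03 + 0.97 * 0.1)
  expect_equal(sum(nxt), 1)
  # several states all normalise
  for (cnt in list(c(2, 0), c(1, 1), c(0, 3))) {
    expect_equal(sum(urn_next_prob(cnt, p, theta = 0.1)), 1)
  }
  expect_error(urn_next_prob(c(0, 0), p, theta = 1),
    class = "famlr_validation_error"
  )
})

test_that("theta = 0 pair probabilities reduce to the classical table", {
  p <- c(a = 0.1, b = 0.3, c = 0.2, d = 0.4)
  cases <- list(
    list("aa,aa", c("a", "a"), c("a", "a")),
    list("aa,ab", c("a", "a"), c("a", "b")),
    list("aa,bb", c("a", "a"), c("b", "b")),
    list("ab,ab", c("a", "b"), c("a", "b")),
    list("ab,ac", c("a", "b"), c("a", "c")),
    list("ab,cd", c("a", "b"), c("c", "d"))
  )
  for (cs in cases) {
    for (j in 0:2) {
      k <- c(0, 0, 0)
      k[j + 1] <- 1
      expect_equal(
        genotype_pair_prob(cs[[2]], cs[[3]], k, p, theta = 0),
        classic_pair_prob(cs[[1]], j, p),
        tolerance = 1e-12,
        label = paste("pattern", cs[[1]], "j =", j)
      )
    }
  }
})

test_that("theta > 0 unrelated probabilities match Balding-Nichols algebra", {
  p <- c(a = 0.1, b = 0.25, c = 0.65)
  for (theta in c(0.01, 0.03, 0.1)) {
    expect_equal(
      genotype_pair_prob(c("a", "a"), c("a", "a"), "unrelated", p, theta),
      bn_unrelated_match("aa,aa", p, theta),
      tolerance = 1e-12
    )
    expect_equal(
      genotype_pair_prob(c("a", "b"), c("a", "b"), "unrelated", p, theta),
      bn_unrelated_match("ab,ab", p, theta),
      tolerance = 1e-12
    )
  }
})

test_that("pair probabilities are exchangeable in the two individuals", {
  set.seed(42)
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  for (rep in 1:20) {
    g1 <- sample(names(p), 2, replace = TRUE)
    g2 <- sample(names(p), 2, replace = TRUE)
    rel <- sample(relationships()$relationship, 1)
    theta <- sample(c(0, 0.01, 0.1), 1)
    expect_equal(
      genotype_pair_prob(g1, g2, rel, p, theta),
      genotype_pair_prob(g2, g1, rel, p, theta),
      tolerance = 1e-14
    )
    expect_equal(
      genotype_pair_prob(g1, g2, rel, p, theta),
      genotype_pair_prob(rev(g1), g2, rel, p, theta),
      tolerance = 1e-14
    )
  }
})

test_that("pair states sum to one and marginalise to single genotypes", {
  p <- c(a = 0.3, b = 0.7)
  for (theta in c(0, 0.05)) {
    st <- enumerate_pair_states("sibling", p, theta)
    expect_equal(sum(st$prob), 1, tolerance = 1e-12)
    # marginal over individual 2 = genotype probability of individual 1
    m_aa <- sum(st$prob[st$g1_a == "a" & st$g1_b == "a"])
    expect_equal(m_aa, 0.3 * (theta + (1 - theta) * 0.3), tolerance = 1e-12)
    m_ab <- sum(st$prob[st$g1_a == "a" & st$g1_b == "b"])
    expect_equal(m_ab, 2 * 0.3 * 0.7 * (1 - theta), tolerance = 1e-12)
  }
})

test_that("zero-frequency observed alleles are rejected", {
  p <- c(a = 0, b = 1)
  expect_error(
    genotype_pair_prob(c("a", "b"), c("b", "b"), "sibling", p),
    class = "famlr_validation_error"
  )
  expect_error(
    genotype_pair_prob(c("b", "b"), c("b", "b"), "sibling", c(a = 0.5, b = 0.4)),
    class = "famlr_validation_error"
  )
})
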