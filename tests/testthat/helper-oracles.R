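# Independent oracles for the genotype-pair probability model, written as
# explicit closed-form algebra (not shared with the package internals).

# Classical theta = 0 unordered two-individual genotype probabilities by
# IBD state j (0, 1, 2) for the five distinct patterns; a, b, c, d are
# distinct alleles with frequencies from the named vector p.
classic_pair_prob <- function(pattern, j, p) {
  pa <- unname(p["a"])
  pb <- unname(p["b"])
  pc <- unname(p["c"])
  pd <- unname(p["d"])
  tab <- list(
    "aa,aa" = c(pa^4, pa^3, pa^2),
    "aa,ab" = c(2 * pa^3 * pb, pa^2 * pb, 0),
    "aa,bb" = c(pa^2 * pb^2, 0, 0),
    "ab,ab" = c(4 * pa^2 * pb^2, pa * pb * (pa + pb), 2 * pa * pb),
    "ab,ac" = c(4 * pa^2 * pb * pc, pa * pb * pc, 0),
    "ab,cd" = c(4 * pa * pb * pc * pd, 0, 0)
  )
  tab[[pattern]][j + 1]
}

# Balding-Nichols closed forms for unrelated pairs at coancestry theta:
# the genotype probability times the published conditional match
# probability for observing the same genotype again.
bn_unrelated_match <- function(pattern, p, theta) {
  pa <- unname(p["a"])
  pb <- unname(p["b"])
  t <- theta
  den <- (1 + t) * (1 + 2 * t)
  if (pattern == "aa,aa") {
    pa * (t + (1 - t) * pa) *
      (2 * t + (1 - t) * pa) * (3 * t + (1 - t) * pa) / den
  } else if (pattern == "ab,ab") {
    2 * pa * pb * (1 - t) *
      2 * (t + (1 - t) * pa) * (t + (1 - t) * pb) / den
  } else {
    stop("pattern not tabulated")
  }
}

# ln LR closed forms at theta = 0
sib_lr_homhom <- function(pa) 1 / 4 + 1 / (2 * pa) + 1 / (4 * pa^2)
po_lr_shared <- function(pa) 1 / (4 * pa)

# Definitional Weir-Cockerham (1984) variance components for a single
# biallelic locus, two populations, HWE heterozygosity -- written from the
# published component definitions, summing the two alleles explicitly.
wc_biallelic_oracle <- function(p1, p2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  comp <- function(pA, pB) {
    pbar <- (n1 * pA + n2 * pB) / (n1 + n2)
    s2 <- (n1 * (pA - pbar)^2 + n2 * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * 2 * pA * (1 - pA) + n2 * 2 * pB * (1 - pB)) / (n1 + n2)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
      ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }
  tot <- comp(p1, p2) + comp(1 - p1, 1 - p2)
  tot[1] / sum(tot)
}
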