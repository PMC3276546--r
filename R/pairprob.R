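#' Sequential Dirichlet (urn) probability of the next founder allele
#'
#' Under the coancestry-corrected allele-frequency model, founder alleles
#' are drawn sequentially: after `m = sum(counts)` draws with `counts[i]`
#' copies of allele `i` observed, the next draw is allele `i` with
#' probability \deqn{\frac{m_i \theta + (1-\theta) p_i}{1 + (m-1)\theta}.}
#' With `theta = 0` this is sampling from `p`; as `theta` grows, previously
#' drawn alleles are increasingly likely to recur, inducing the
#' within-population correlation described by the coancestry coefficient.
#'
#' @param counts Non-negative per-allele draw counts (same length as `p`).
#' @param p Locus allele-frequency vector summing to 1.
#' @param theta Coancestry coefficient in `[0, 1)`.
#' @return A probability vector summing to 1, named as `p`.
#' @examples
#' p <- c(a = 0.1, b = 0.9)
#' urn_next_prob(c(0, 0), p, theta = 0.03) # first draw: p itself
#' urn_next_prob(c(1, 0), p, theta = 0.03) # P(a) = 0.03 + 0.97 * 0.1
#' @export
urn_next_prob <- function(counts, p, theta = 0) {
  if (length(counts) != length(p) || any(counts < 0)) {
    abort("`counts` must be non-negative and match `p` in length",
      class = "famlr_validation_error"
    )
  }
  if (theta < 0 || theta >= 1) {
    if (!(theta == 1 && sum(counts) > 0)) {
      abort("theta must be in [0, 1)", class = "famlr_validation_error")
    }
  }
  if (abs(sum(p) - 1) > 1e-6) {
    abort("`p` must sum to 1", class = "famlr_validation_error")
  }
  m <- sum(counts)
  denom <- 1 + (m - 1) * theta
  if (denom <= 0) {
    abort("degenerate urn state (theta = 1 with no prior draws)",
      class = "famlr_validation_error"
    )
  }
  out <- (counts * theta + (1 - theta) * p) / denom
  setNames(out, names(p))
}

# Probability of an ordered sequence of founder-allele draws (integer
# indices into p) under the sequential urn rule. Exchangeable in the draw
# order.
.seq_prob <- function(idx, p, theta) {
  cnt <- numeric(length(p))
  m <- 0
  pr <- 1
  for (a in idx) {
    pr <- pr * (cnt[a] * theta + (1 - theta) * p[a]) / (1 + (m - 1) * theta)
    cnt[a] <- cnt[a] + 1
    m <- m + 1
  }
  pr
}

# P(unordered genotype pair | exactly j alleles shared IBD). g1, g2 are
# sorted integer pairs. Founder lineages number 4 - j: an IBD-shared allele
# is a single founder draw copied to both individuals.
.pair_prob_j <- function(g1, g2, j, p, theta) {
  if (j == 2L) {
    if (g1[1] != g2[1] || g1[2] != g2[2]) {
      return(0)
    }
    pr <- .seq_prob(g1, p, theta)
    if (g1[1] == g1[2]) pr else 2 * pr
  } else if (j == 1L) {
    s_vals <- intersect(unique(g1), unique(g2))
    if (length(s_vals) == 0) {
      return(0)
    }
    tot <- 0
    for (s in s_vals) {
      a <- if (g1[1] == s) g1[2] else g1[1]
      b <- if (g2[1] == s) g2[2] else g2[1]
      tot <- tot + .seq_prob(c(s, a, b), p, theta)
    }
    tot
  } else {
    m1 <- if (g1[1] == g1[2]) 1 else 2
    m2 <- if (g2[1] == g2[2]) 1 else 2
    m1 * m2 * .seq_prob(c(g1, g2), p, theta)
  }
}

# core: no validation, integer genotypes, kvec = c(k0, k1, k2)
.pair_prob <- function(g1, g2, kvec, theta, p) {
  g1 <- sort(g1)
  g2 <- sort(g2)
  pr <- kvec[1] * .pair_prob_j(g1, g2, 0L, p, theta)
  if (kvec[2] > 0) pr <- pr + kvec[2] * .pair_prob_j(g1, g2, 1L, p, theta)
  if (kvec[3] > 0) pr <- pr + kvec[3] * .pair_prob_j(g1, g2, 2L, p, theta)
  unname(pr)
}

.genotype_to_idx <- function(g, p) {
  if (is.character(g)) {
    i <- match(g, names(p))
    if (anyNA(i)) {
      abort(paste0(
        "allele(s) not in frequency vector: ",
        paste(g[is.na(i)], collapse = ", ")
      ), class = "famlr_validation_error")
    }
    i
  } else {
    as.integer(g)
  }
}

#' Joint probability of two genotypes given a relationship and coancestry
#'
#' Probability of the unordered genotype pair at one locus,
#' \eqn{\sum_j k_j P_j(G;\theta,p)}, where \eqn{P_j} conditions on exactly
#' `j` alleles shared identical by descent and founder alleles follow the
#' sequential urn rule of [urn_next_prob()]. At `theta = 0` this reduces to
#' the classical Hardy-Weinberg/Mendelian two-individual probabilities.
#'
#' @param g1,g2 Length-2 genotypes: allele labels matching `names(p)` or
#'   integer indices into `p`. Order within and between genotypes is
#'   irrelevant.
#' @param relationship A relationship name or `(k0, k1, k2)` triple.
#' @param p Locus allele-frequency vector summing to 1; every observed
#'   allele must have positive frequency (apply [floor_frequencies()]
#'   first if needed).
#' @param theta Coancestry coefficient in `[0, 1)`.
#' @return A probability.
#' @examples
#' p <- c(a = 0.1, b = 0.9)
#' genotype_pair_prob(c("a", "a"), c("a", "a"), "unrelated", p) # p^4 = 1e-4
#' genotype_pair_prob(c("a", "a"), c("a", "a"), "sibling", p)
#' @export
genotype_pair_prob <- function(g1, g2, relationship, p, theta = 0) {
  kvec <- as_ibd(relationship)
  if (theta < 0 || theta >= 1) {
    abort("theta must be in [0, 1)", class = "famlr_validation_error")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    abort("`p` must sum to 1", class = "famlr_validation_error")
  }
  i1 <- .genotype_to_idx(g1, p)
  i2 <- .genotype_to_idx(g2, p)
  if (length(i1) != 2 || length(i2) != 2) {
    abort("genotypes must have exactly two alleles", class = "famlr_validation_error")
  }
  if (any(p[c(i1, i2)] <= 0)) {
    abort(
      "observed allele has zero frequency; apply floor_frequencies() first",
      class = "famlr_validation_error"
    )
  }
  .pair_prob(i1, i2, kvec, theta, unname(p))
}

#' Enumerate all genotype-pair states and their probabilities
#'
#' All unordered genotype pairs over the allele universe of `p`, with their
#' probabilities under [genotype_pair_prob()]. For any valid
#' `(relationship, theta, p)` the probabilities sum to 1.
#'
#' @inheritParams genotype_pair_prob
#' @return A tibble with columns `g1_a`, `g1_b`, `g2_a`, `g2_b` (allele
#'   labels) and `prob`.
#' @export
enumerate_pair_states <- function(relationship, p, theta = 0) {
  kvec <- as_ibd(relationship)
  labs <- names(p) %||% as.character(seq_along(p))
  K <- length(p)
  gts <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  gts <- gts[order(gts[, 1], gts[, 2]), , drop = FALSE] # (row <= col)
  n_g <- nrow(gts)
  rows <- vector("list", n_g * n_g)
  pos <- 0L
  pu <- unname(p)
  for (i in seq_len(n_g)) {
    for (j in seq_len(n_g)) {
      g1 <- c(gts[i, 1], gts[i, 2])
      g2 <- c(gts[j, 1], gts[j, 2])
      pos <- pos + 1L
      rows[[pos]] <- tibble::tibble(
        g1_a = labs[g1[1]], g1_b = labs[g1[2]],
        g2_a = labs[g2[1]], g2_b = labs[g2[2]],
        prob = .pair_prob(g1, g2, kvec, theta, pu)
      )
    }
  }
  dplyr::bind_rows(rows)
}
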