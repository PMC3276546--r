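# Non-inbred pedigrees for gene dropping. Founders are ids 1..n_founders;
# descendants list (id, father, mother) in drop order; `pair` gives the two
# target members returned as the simulated pair.
.pedigrees <- list(
  "unrelated" = list(founders = 2L, members = NULL, pair = c(1L, 2L)),
  "parent-offspring" = list(
    founders = 2L,
    members = matrix(c(3L, 1L, 2L), ncol = 3, byrow = TRUE),
    pair = c(1L, 3L)
  ),
  "sibling" = list(
    founders = 2L,
    members = matrix(c(
      3L, 1L, 2L,
      4L, 1L, 2L
    ), ncol = 3, byrow = TRUE),
    pair = c(3L, 4L)
  ),
  "half-sibling" = list(
    founders = 3L,
    members = matrix(c(
      4L, 1L, 2L,
      5L, 1L, 3L
    ), ncol = 3, byrow = TRUE),
    pair = c(4L, 5L)
  ),
  # grandparent couple (1,2) -> sibling parents (5,6) married to founders
  # (3,4) -> first cousins (7,8)
  "first-cousin" = list(
    founders = 4L,
    members = matrix(c(
      5L, 1L, 2L,
      6L, 1L, 2L,
      7L, 5L, 3L,
      8L, 6L, 4L
    ), ncol = 3, byrow = TRUE),
    pair = c(7L, 8L)
  ),
  # one further generation: first-cousin parents -> second cousins
  "second-cousin" = list(
    founders = 6L,
    members = matrix(c(
      7L, 1L, 2L,
      8L, 1L, 2L,
      9L, 7L, 3L,
      10L, 8L, 4L,
      11L, 9L, 5L,
      12L, 10L, 6L
    ), ncol = 3, byrow = TRUE),
    pair = c(11L, 12L)
  )
)

# Vectorised gene dropping for one locus: founder alleles i.i.d. from
# pfreq, descendants receive one uniformly chosen allele per parent.
# Returns integer allele indices for the target pair plus the realised
# IBD-sharing count obtained by tracking founder-lineage labels.
.gene_drop_locus <- function(ped, n, pfreq) {
  K <- length(pfreq)
  nf <- ped$founders
  V <- matrix(
    sample.int(K, n * 2L * nf, replace = TRUE, prob = pfreq),
    nrow = n
  )
  n_ids <- nf + if (is.null(ped$members)) 0L else nrow(ped$members)
  lin <- vector("list", n_ids)
  for (i in seq_len(nf)) {
    lin[[i]] <- cbind(rep(2L * i - 1L, n), rep(2L * i, n))
  }
  if (!is.null(ped$members)) {
    rows <- seq_len(n)
    for (m in seq_len(nrow(ped$members))) {
      id <- ped$members[m, 1]
      fa <- lin[[ped$members[m, 2]]]
      mo <- lin[[ped$members[m, 3]]]
      g1 <- fa[cbind(rows, rbinom(n, 1L, 0.5) + 1L)]
      g2 <- mo[cbind(rows, rbinom(n, 1L, 0.5) + 1L)]
      lin[[id]] <- cbind(g1, g2)
    }
  }
  l1 <- lin[[ped$pair[1]]]
  l2 <- lin[[ped$pair[2]]]
  rows <- seq_len(n)
  list(
    a1_1 = V[cbind(rows, l1[, 1])],
    a1_2 = V[cbind(rows, l1[, 2])],
    a2_1 = V[cbind(rows, l2[, 1])],
    a2_2 = V[cbind(rows, l2[, 2])],
    ibd = (l1[, 1] == l2[, 1]) + (l1[, 1] == l2[, 2]) +
      (l1[, 2] == l2[, 1]) + (l1[, 2] == l2[, 2])
  )
}

# Vectorised urn-model sampling for one locus at coancestry theta: draw the
# IBD state j ~ (k0, k1, k2), then 4 - j founder alleles sequentially.
# Sequential draws use the copy/fresh decomposition of the urn rule: after
# m draws the next is a copy of a uniformly chosen previous draw with
# probability m * theta / (1 + (m - 1) * theta), else fresh from pfreq.
.urn_pairs_locus <- function(kvec, theta, n, pfreq) {
  K <- length(pfreq)
  j <- sample.int(3L, n, replace = TRUE, prob = kvec) - 1L
  d1 <- sample.int(K, n, replace = TRUE, prob = pfreq)
  cp2 <- runif(n) < theta
  d2 <- ifelse(cp2, d1, sample.int(K, n, replace = TRUE, prob = pfreq))
  cp3 <- runif(n) < 2 * theta / (1 + theta)
  src3 <- sample.int(2L, n, replace = TRUE)
  prev3 <- ifelse(src3 == 1L, d1, d2)
  d3 <- ifelse(cp3, prev3, sample.int(K, n, replace = TRUE, prob = pfreq))
  cp4 <- runif(n) < 3 * theta / (1 + 2 * theta)
  src4 <- sample.int(3L, n, replace = TRUE)
  prev4 <- ifelse(src4 == 1L, d1, ifelse(src4 == 2L, d2, d3))
  d4 <- ifelse(cp4, prev4, sample.int(K, n, replace = TRUE, prob = pfreq))

  a1_1 <- d1
  a1_2 <- d2
  a2_1 <- ifelse(j == 0L, d3, d1)
  a2_2 <- ifelse(j == 0L, d4, ifelse(j == 1L, d3, d2))
  list(a1_1 = a1_1, a1_2 = a1_2, a2_1 = a2_1, a2_2 = a2_2, ibd = j)
}

#' Simulate genotype pairs for a relationship
#'
#' Simulates `n_pairs` pairs of diploid genotypes over the panel's loci for
#' a named relationship (or explicit IBD triple). With `theta_true = 0`
#' (the default) founder alleles are drawn independently from the
#' population's frequencies and dropped through the relationship's pedigree
#' ("gene dropping"), which implicitly places the pair in a population with
#' zero coancestry. With `theta_true > 0`, genotype pairs are drawn from
#' the joint two-individual genotype probabilities under the sequential urn
#' model (see [genotype_pair_prob()]), so unrelated pairs share alleles at
#' the rate a structured population implies.
#'
#' @param panel A [freq_panel()].
#' @param population Population label whose frequencies drive the
#'   simulation (the "true" population).
#' @param relationship Relationship name or `(k0, k1, k2)` triple.
#' @param n_pairs Number of pairs (>= 1).
#' @param theta_true True coancestry coefficient in `[0, 1)`.
#' @param seed Optional integer seed; when given, the RNG state is isolated
#'   and restored (same seed, same configuration: identical output).
#' @param track_ibd Include the per-locus IBD state: the realised
#'   founder-lineage sharing count under gene dropping, or the drawn IBD
#'   state under the urn sampler. Diagnostic only; it never influences
#'   sampling.
#' @param method Sampler: `"gene-drop"` (requires `theta_true = 0`) or
#'   `"urn"`. Default chooses gene dropping at `theta_true = 0`, the urn
#'   sampler otherwise.
#' @return A tibble with columns `pair_id`, `locus`, `a1_1`, `a1_2`,
#'   `a2_1`, `a2_2` (allele labels) and, if `track_ibd`, `ibd`.
#' @examples
#' panel <- generate_equifrequent_panel(3, 4, n = 100)
#' simulate_pairs(panel, "pop1", "sibling", 5, seed = 1)
#' @export
simulate_pairs <- function(panel, population, relationship, n_pairs,
                           theta_true = 0, seed = NULL, track_ibd = FALSE,
                           method = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  .check_pop(panel, population)
  if (!is.numeric(n_pairs) || n_pairs < 1) {
    abort("`n_pairs` must be >= 1", class = "famlr_config_error")
  }
  n_pairs <- as.integer(n_pairs)
  if (theta_true < 0 || theta_true >= 1) {
    abort("`theta_true` must be in [0, 1)", class = "famlr_config_error")
  }
  kvec <- as_ibd(relationship)
  method <- method %||% (if (theta_true == 0) "gene-drop" else "urn")
  method <- match.arg(method, c("gene-drop", "urn"))
  if (method == "gene-drop") {
    if (theta_true != 0) {
      abort("gene dropping requires theta_true = 0 (use method = 'urn')",
        class = "famlr_config_error"
      )
    }
    if (!is.character(relationship)) {
      abort("gene dropping needs a named relationship (pedigree definition)",
        class = "famlr_config_error"
      )
    }
    ped <- .pedigrees[[.match_relationship(relationship)]]
  }

  flist <- .freq_list(panel, population)
  run <- function() {
    res <- vector("list", length(flist))
    for (l in seq_along(flist)) {
      q <- flist[[l]]
      draw <- if (method == "gene-drop") {
        .gene_drop_locus(ped, n_pairs, unname(q))
      } else {
        .urn_pairs_locus(kvec, theta_true, n_pairs, unname(q))
      }
      labs <- names(q)
      res[[l]] <- tibble::tibble(
        pair_id = seq_len(n_pairs),
        locus = names(flist)[l],
        a1_1 = labs[draw$a1_1],
        a1_2 = labs[draw$a1_2],
        a2_1 = labs[draw$a2_1],
        a2_2 = labs[draw$a2_2],
        ibd = draw$ibd
      )
    }
    out <- dplyr::bind_rows(res)
    out <- dplyr::arrange(out, .data$pair_id, match(.data$locus, names(flist)))
    if (!track_ibd) out$ibd <- NULL
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
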