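#' Per-locus gene diversity (expected heterozygosity)
#'
#' Gene diversity at a locus is \eqn{h_l = 1 - \sum_i \hat p_{l,i}^2}, the
#' probability that two alleles drawn at random differ. The plug-in form is
#' the default; `corrected = TRUE` applies the \eqn{2n/(2n-1)} small-sample
#' factor.
#'
#' @param panel A [freq_panel()].
#' @param populations Population labels to include; default all.
#' @param corrected Apply the \eqn{2n/(2n-1)} bias correction? Default
#'   `FALSE`.
#' @return A tibble with columns `population`, `locus`, `h`.
#' @seealso [panel_diversity()] for per-population averages.
#' @export
gene_diversity <- function(panel, populations = NULL, corrected = FALSE) {
  populations <- populations %||% panel$populations
  .check_pop(panel, populations)
  out <- panel$freq |>
    dplyr::filter(.data$population %in% populations) |>
    dplyr::summarise(
      h = 1 - sum(.data$frequency^2),
      .by = c("population", "locus")
    )
  if (corrected) {
    n2 <- 2 * panel$sizes$n[match(out$population, panel$sizes$population)]
    out$h <- out$h * n2 / (n2 - 1)
  }
  out
}

#' Per-locus profile entropy in bits
#'
#' Shannon entropy \eqn{S_l = -\sum_i \hat p_{l,i} \log_2 \hat p_{l,i}}
#' (with \eqn{0\log 0 = 0}) measures the information content of a locus; the
#' haplotype total \eqn{\sum_l S_l} is the number of bits needed to encode a
#' single-allele-per-locus profile and the diploid total is twice that.
#'
#' @inheritParams gene_diversity
#' @return A tibble with columns `population`, `locus`, `bits`.
#' @export
profile_entropy <- function(panel, populations = NULL) {
  populations <- populations %||% panel$populations
  .check_pop(panel, populations)
  panel$freq |>
    dplyr::filter(.data$population %in% populations) |>
    dplyr::summarise(
      bits = -sum(ifelse(.data$frequency > 0,
        .data$frequency * log2(.data$frequency), 0
      )),
      .by = c("population", "locus")
    )
}

#' Per-population diversity and entropy summaries
#'
#' Averages [gene_diversity()] over loci (`h_bar`) and totals
#' [profile_entropy()] per haplotype and per diploid profile.
#'
#' @inheritParams gene_diversity
#' @return A tibble with one row per population: `population`, `h_bar`,
#'   `entropy_haploid_bits`, `entropy_diploid_bits`.
#' @export
panel_diversity <- function(panel, populations = NULL, corrected = FALSE) {
  h <- gene_diversity(panel, populations, corrected) |>
    dplyr::summarise(h_bar = mean(.data$h), .by = "population")
  s <- profile_entropy(panel, populations) |>
    dplyr::summarise(entropy_haploid_bits = sum(.data$bits), .by = "population")
  dplyr::left_join(h, s, by = "population") |>
    dplyr::mutate(entropy_diploid_bits = 2 * .data$entropy_haploid_bits)
}

#' Weir-Cockerham FST between two population samples
#'
#' Multi-allele, multi-locus variance-components estimator of Weir and
#' Cockerham (1984), combined as a ratio of sums over alleles and loci.
#' Because only allele frequencies (not genotype counts) are available, the
#' within-population heterozygosity term is taken at its Hardy-Weinberg
#' expectation \eqn{2\hat p(1-\hat p)}. The raw estimate can be negative;
#' the reported estimate truncates at zero.
#'
#' @param panel A [freq_panel()].
#' @param pop_a,pop_b Population labels in the panel.
#' @return A one-row tibble: `pop_a`, `pop_b`, `fst_raw`, `fst`
#'   (`max(fst_raw, 0)`), and `estimable` (`FALSE` when the denominator
#'   vanishes, e.g. a single locus monomorphic for the same allele in both
#'   populations).
#' @export
fst_wc <- function(panel, pop_a, pop_b) {
  .check_pop(panel, c(pop_a, pop_b))
  n1 <- .panel_size(panel, pop_a)
  n2 <- .panel_size(panel, pop_b)
  fa <- .freq_list(panel, pop_a)
  fb <- .freq_list(panel, pop_b)

  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)

  A <- B <- C <- 0
  for (l in seq_along(fa)) {
    p1 <- unname(fa[[l]])
    p2 <- unname(fb[[l]])
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + sum(a)
    B <- B + sum(b)
    C <- C + sum(cc)
  }
  denom <- A + B + C
  if (!is.finite(denom) || abs(denom) < 1e-12) {
    return(tibble::tibble(
      pop_a = pop_a, pop_b = pop_b,
      fst_raw = NA_real_, fst = NA_real_, estimable = FALSE
    ))
  }
  raw <- A / denom
  tibble::tibble(
    pop_a = pop_a, pop_b = pop_b,
    fst_raw = raw, fst = max(raw, 0), estimable = TRUE
  )
}

#' Pairwise FST matrix for a panel
#'
#' [fst_wc()] for every unordered pair of populations, in panel order.
#'
#' @param panel A [freq_panel()].
#' @return A tibble with one row per unordered population pair.
#' @export
fst_matrix <- function(panel) {
  pops <- panel$populations
  if (length(pops) < 2) {
    abort("need at least two populations", class = "famlr_validation_error")
  }
  pairs <- utils::combn(pops, 2)
  purrr::map_dfr(
    seq_len(ncol(pairs)),
    function(i) fst_wc(panel, pairs[1, i], pairs[2, i])
  )
}
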