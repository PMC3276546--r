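#' Generate an equi-frequent marker panel
#'
#' A single-population panel of `n_loci` unlinked loci, each with
#' `alleles_per_locus` equally frequent alleles: 10 alleles per locus gives
#' an STR-like panel (per-locus gene diversity 0.9), 2 alleles a SNP-like
#' panel (0.5).
#'
#' @param n_loci Number of loci (>= 1).
#' @param alleles_per_locus Alleles per locus (>= 2).
#' @param n Diploid sample size recorded for the population (default 200).
#' @param population Population label (default `"pop1"`).
#' @return A [freq_panel()].
#' @export
generate_equifrequent_panel <- function(n_loci, alleles_per_locus, n = 200,
                                        population = "pop1") {
  stopifnot(n_loci >= 1, alleles_per_locus >= 2, n >= 1)
  loci <- sprintf("L%02d", seq_len(n_loci))
  alleles <- sprintf("A%02d", seq_len(alleles_per_locus))
  freq <- tidyr::expand_grid(
    population = population, locus = loci, allele = alleles
  )
  freq$frequency <- 1 / alleles_per_locus
  freq_panel(freq, sizes = tibble::tibble(population = population, n = n))
}

# One Dirichlet draw with concentration alpha (zero entries stay zero).
.rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- rgamma(sum(pos), shape = alpha[pos])
  g / sum(g)
}

#' Generate populations diverged from a base panel
#'
#' For each divergence value `F > 0`, a derived population's frequencies at
#' each locus are drawn from a Dirichlet distribution with concentration
#' \eqn{p_{base} (1-F)/F} — the same parameterisation as the
#' confidence-interval variance model, so `F` plays the role of a true
#' coancestry/divergence coefficient and the derived frequencies are
#' centred on the base. `F = 0` returns an exact copy of the base
#' frequencies.
#'
#' @param base A single-population [freq_panel()] (or one population of a
#'   larger panel, named via `base_pop`).
#' @param f Numeric vector of divergence values in `[0, 1)`, one derived
#'   population per element.
#' @param n Diploid sample sizes recorded for the derived populations
#'   (recycled).
#' @param pop_names Labels for the derived populations; default
#'   `"F<value>"`.
#' @param base_pop Which population of `base` to diverge from; default its
#'   first.
#' @param seed Optional seed (isolated as in [simulate_pairs()]).
#' @return A [freq_panel()] containing the derived populations.
#' @export
generate_diverged_panels <- function(base, f, n = 200, pop_names = NULL,
                                     base_pop = NULL, seed = NULL) {
  stopifnot(inherits(base, "freq_panel"))
  if (any(f < 0) || any(f >= 1)) {
    abort("divergence values must be in [0, 1)", class = "famlr_config_error")
  }
  base_pop <- base_pop %||% base$populations[1]
  flist <- .freq_list(base, base_pop)
  pop_names <- pop_names %||% paste0("F", format(f, trim = TRUE))
  if (anyDuplicated(pop_names) > 0) {
    abort("derived population names must be unique", class = "famlr_config_error")
  }
  n <- rep_len(n, length(f))

  run <- function() {
    rows <- vector("list", length(f))
    for (i in seq_along(f)) {
      per_locus <- lapply(flist, function(p) {
        if (f[i] == 0) {
          unname(p)
        } else {
          .rdirichlet1(unname(p) * (1 - f[i]) / f[i])
        }
      })
      rows[[i]] <- tibble::tibble(
        population = pop_names[i],
        locus = rep(names(flist), lengths(flist)),
        allele = unlist(lapply(flist, names), use.names = FALSE),
        frequency = unlist(per_locus, use.names = FALSE)
      )
    }
    freq_panel(
      dplyr::bind_rows(rows),
      sizes = tibble::tibble(population = pop_names, n = n),
      sum_tol = 1e-6
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Combine frequency panels over populations
#'
#' Stacks panels that share a locus set into one multi-population panel
#' (allele universes are merged).
#'
#' @param ... `freq_panel` objects with disjoint population labels.
#' @return A [freq_panel()].
#' @export
bind_panels <- function(...) {
  panels <- list(...)
  stopifnot(all(vapply(panels, inherits, TRUE, "freq_panel")))
  freq <- dplyr::bind_rows(lapply(panels, function(x) x$freq))
  sizes <- dplyr::bind_rows(lapply(panels, function(x) x$sizes))
  freq_panel(freq, sizes = sizes, sum_tol = 1e-6)
}

#' Built-in synthetic five-population fixture panel
#'
#' A deterministic 5-population, 13-locus, 10-allele panel emulating the
#' structure of published forensic STR frequency tables: four populations
#' diverged from a common base by increasing amounts (F = 0, 0.015, 0.02,
#' 0.04) plus one strongly diverged, low-diversity population (`popE`,
#' F = 0.07 applied to a sharpened base distribution) that mimics the
#' pattern of a population with reduced gene diversity at these loci. The
#' panel is synthetic: it reproduces the statistical shape the analysis
#' assumes, not any real population's frequencies.
#'
#' @return A [freq_panel()] with populations `popA` ... `popE`.
#' @export
codis_like_fixture <- function() {
  withr::with_seed(20120209, {
    n_loci <- 13
    k <- 10
    loci <- sprintf("L%02d", seq_len(n_loci))
    alleles <- sprintf("A%02d", seq_len(k))
    base_p <- lapply(seq_len(n_loci), function(i) .rdirichlet1(rep(1.5, k)))
    base <- freq_panel(
      tibble::tibble(
        population = "base",
        locus = rep(loci, each = k),
        allele = rep(alleles, n_loci),
        frequency = unlist(base_p)
      ),
      sizes = tibble::tibble(population = "base", n = 200),
      sum_tol = 1e-6
    )
    abcd <- generate_diverged_panels(
      base,
      f = c(0, 0.015, 0.02, 0.04),
      n = c(200, 195, 180, 170),
      pop_names = c("popA", "popB", "popC", "popD")
    )
    # low-diversity population: sharpen the base (p^2.2, renormalised)
    # before the Dirichlet divergence draw
    sharp <- freq_panel(
      tibble::tibble(
        population = "sharp",
        locus = rep(loci, each = k),
        allele = rep(alleles, n_loci),
        frequency = unlist(lapply(base_p, function(p) p^2.2 / sum(p^2.2)))
      ),
      sizes = tibble::tibble(population = "sharp", n = 200),
      sum_tol = 1e-6
    )
    pop_e <- generate_diverged_panels(sharp,
      f = 0.07, n = 105,
      pop_names = "popE"
    )
    bind_panels(abcd, pop_e)
  })
}
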