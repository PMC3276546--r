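#' Floor the frequencies of observed alleles
#'
#' When likelihood ratios are evaluated under an assumed population whose
#' sample lacks an allele carried by the tested pair, the raw frequency is
#' zero and the likelihood is undefined. `floor_frequencies()` raises every
#' observed allele below `floor` up to `floor` and rescales the remaining
#' alleles so the vector still sums to 1. The number of raised alleles is
#' returned in the `n_floored` attribute.
#'
#' @param p Locus allele-frequency vector summing to 1.
#' @param observed Allele labels (matching `names(p)`) or integer indices of
#'   the alleles appearing in the genotype pair.
#' @param floor Minimum frequency, in `(0, 0.05]` and below
#'   `1/length(p)`.
#' @return The adjusted vector (with attribute `n_floored`).
#' @examples
#' floor_frequencies(c(a = 0, b = 1), "a", floor = 0.001)
#' @export
floor_frequencies <- function(p, observed, floor) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0 || floor > 0.05) {
    abort("`floor` must be in (0, 0.05]", class = "famlr_config_error")
  }
  if (floor >= 1 / length(p)) {
    abort("`floor` must be below 1/(number of alleles)",
      class = "famlr_config_error"
    )
  }
  obs <- .genotype_to_idx2(observed, p)
  low <- obs[p[obs] < floor]
  low <- unique(low)
  out <- unname(p)
  if (length(low) > 0) {
    out[low] <- floor
    rest <- setdiff(seq_along(p), low)
    out[rest] <- out[rest] * (1 - floor * length(low)) / sum(p[rest])
  }
  out <- setNames(out, names(p))
  attr(out, "n_floored") <- length(low)
  out
}

.genotype_to_idx2 <- function(g, p) {
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

#' Single-locus likelihood ratio for a relationship versus unrelated
#'
#' \eqn{LR = P(G \mid \text{related}, \theta) / P(G \mid \text{unrelated},
#' \theta)} for one locus, with both probabilities from
#' [genotype_pair_prob()]. An LR of zero is possible (e.g. parent-offspring
#' with no shared allele); the unrelated relationship gives LR = 1 for any
#' pair.
#'
#' @inheritParams genotype_pair_prob
#' @param theta_assumed Coancestry coefficient used in the probability
#'   calculations.
#' @return A non-negative likelihood ratio.
#' @examples
#' p <- c(a = 0.1, b = 0.5, c = 0.4)
#' locus_lr(c("a", "b"), c("a", "c"), "parent-offspring", p) # 1/(4 * 0.1)
#' @export
locus_lr <- function(g1, g2, relationship, p, theta_assumed = 0.01) {
  kvec <- as_ibd(relationship)
  if (abs(sum(p) - 1) > 1e-6) {
    abort("`p` must sum to 1", class = "famlr_validation_error")
  }
  i1 <- .genotype_to_idx2(g1, p)
  i2 <- .genotype_to_idx2(g2, p)
  if (any(p[c(i1, i2)] <= 0)) {
    abort(
      "observed allele has zero frequency; apply floor_frequencies() first",
      class = "famlr_validation_error"
    )
  }
  pu <- unname(p)
  den <- .pair_prob_j(sort(i1), sort(i2), 0L, pu, theta_assumed)
  if (den <= 0) {
    abort("internal error: zero unrelated-pair probability after flooring",
      class = "famlr_internal_error"
    )
  }
  .pair_prob(i1, i2, kvec, theta_assumed, pu) / den
}

# ln LR and delta-method variance contribution for one locus.
# g1, g2: sorted integer genotypes; p: floored, unnormalized access fine.
# c_ci: theta_ci + (1 - theta_ci) / (2 n). Gradient by central finite
# differences (step h) on the observed alleles only: the pair probability
# depends on no other component of p, and the covariance
# c * (diag(p) - p p') annihilates the unobserved directions' constants.
.locus_lnlr_stats <- function(g1, g2, kvec, theta, p, c_ci, h = 1e-6) {
  den <- .pair_prob_j(g1, g2, 0L, p, theta)
  num <- kvec[1] * den
  if (kvec[2] > 0) num <- num + kvec[2] * .pair_prob_j(g1, g2, 1L, p, theta)
  if (kvec[3] > 0) num <- num + kvec[3] * .pair_prob_j(g1, g2, 2L, p, theta)
  if (num <= 0) {
    return(c(loglr = -Inf, var = NA_real_))
  }
  loglr <- log(num) - log(den)
  obs <- unique(c(g1, g2))
  grad <- numeric(length(obs))
  for (t in seq_along(obs)) {
    i <- obs[t]
    hi <- p
    hi[i] <- p[i] + h
    lo <- p
    lo[i] <- p[i] - h
    f_hi <- {
      d <- .pair_prob_j(g1, g2, 0L, hi, theta)
      n_ <- kvec[1] * d
      if (kvec[2] > 0) n_ <- n_ + kvec[2] * .pair_prob_j(g1, g2, 1L, hi, theta)
      if (kvec[3] > 0) n_ <- n_ + kvec[3] * .pair_prob_j(g1, g2, 2L, hi, theta)
      log(n_) - log(d)
    }
    f_lo <- {
      d <- .pair_prob_j(g1, g2, 0L, lo, theta)
      n_ <- kvec[1] * d
      if (kvec[2] > 0) n_ <- n_ + kvec[2] * .pair_prob_j(g1, g2, 1L, lo, theta)
      if (kvec[3] > 0) n_ <- n_ + kvec[3] * .pair_prob_j(g1, g2, 2L, lo, theta)
      log(n_) - log(d)
    }
    grad[t] <- (f_hi - f_lo) / (2 * h)
  }
  po <- p[obs]
  v <- c_ci * (sum(grad^2 * po) - sum(grad * po)^2)
  c(loglr = unname(loglr), var = max(v, 0))
}

# Shared engine behind profile_loglr() and lr_confint(). `pairs` is the
# long genotype-pair tibble (pair_id, locus, a1_1, a1_2, a2_1, a2_2).
# Per-locus (genotype-pair, locus) statistics are memoised in `cache`
# (an environment keyed on canonicalised state), which callers may share
# across calls with the same assumed population, relationship and thetas.
.profile_engine <- function(pairs, panel, assumed_pop, kvec, theta_assumed,
                            theta_ci, freq_floor, cache = NULL) {
  .check_pop(panel, assumed_pop)
  missing_loci <- setdiff(unique(pairs$locus), panel$loci)
  if (length(missing_loci) > 0) {
    abort(paste0(
      "locus missing from panel: ",
      paste(missing_loci, collapse = ", ")
    ), class = "famlr_validation_error")
  }
  flist <- .freq_list(panel, assumed_pop)
  n <- .panel_size(panel, assumed_pop)
  c_ci <- theta_ci + (1 - theta_ci) / (2 * n)
  freq_floor <- freq_floor %||% (1 / (2 * n + 1))

  a1 <- pmin(pairs$a1_1, pairs$a1_2)
  b1 <- pmax(pairs$a1_1, pairs$a1_2)
  a2 <- pmin(pairs$a2_1, pairs$a2_2)
  b2 <- pmax(pairs$a2_1, pairs$a2_2)
  s1 <- paste(a1, b1, sep = "/")
  s2 <- paste(a2, b2, sep = "/")
  lo <- pmin(s1, s2)
  hi <- pmax(s1, s2)
  key <- paste(pairs$locus, lo, hi, sep = "|")

  cache <- cache %||% new.env(parent = emptyenv())
  uk <- unique(key)
  new_keys <- uk[!vapply(uk, exists, logical(1), envir = cache, inherits = FALSE)]
  if (length(new_keys) > 0) {
    first <- match(new_keys, key)
    for (t in seq_along(new_keys)) {
      i <- first[t]
      p <- flist[[pairs$locus[i]]]
      g_labs <- c(a1[i], b1[i], a2[i], b2[i])
      novel <- setdiff(unique(g_labs), names(p))
      if (length(novel) > 0) {
        p <- c(p, setNames(rep(0, length(novel)), novel))
      }
      pf <- floor_frequencies(p, unique(g_labs), freq_floor)
      n_floored <- attr(pf, "n_floored")
      i1 <- sort(match(c(a1[i], b1[i]), names(pf)))
      i2 <- sort(match(c(a2[i], b2[i]), names(pf)))
      st <- .locus_lnlr_stats(i1, i2, kvec, theta_assumed, unname(pf), c_ci)
      assign(new_keys[t], c(st, floored = n_floored), envir = cache)
    }
  }
  vals <- matrix(
    unlist(mget(key, envir = cache), use.names = FALSE),
    ncol = 3, byrow = TRUE
  )

  pid <- pairs$pair_id
  ord <- unique(pid)
  f <- factor(pid, levels = ord)
  loglr <- as.vector(rowsum(vals[, 1], f, reorder = FALSE))
  degenerate <- as.vector(rowsum(as.numeric(!is.finite(vals[, 1])), f,
    reorder = FALSE
  )) > 0
  varv <- as.vector(rowsum(ifelse(is.na(vals[, 2]), 0, vals[, 2]), f,
    reorder = FALSE
  ))
  varv[degenerate] <- NA_real_
  n_floored <- as.vector(rowsum(vals[, 3], f, reorder = FALSE))

  tibble::tibble(
    pair_id = ord, loglr = loglr, variance = varv,
    degenerate = degenerate, n_floored = n_floored
  )
}

#' Profile log likelihood ratio over independent loci
#'
#' Sums the per-locus \eqn{\ln LR} over the loci of each genotype pair,
#' evaluating frequencies from the assumed population (with rare-allele
#' flooring, see [floor_frequencies()]). A pair whose LR vanishes at any
#' locus gets `loglr = -Inf` and `degenerate = TRUE`.
#'
#' @param pairs A genotype-pair tibble as produced by [simulate_pairs()]:
#'   columns `pair_id`, `locus`, `a1_1`, `a1_2`, `a2_1`, `a2_2`.
#' @param panel A [freq_panel()].
#' @param assumed_pop Population label whose frequencies are assumed.
#' @param relationship Relationship name or `(k0, k1, k2)` triple for the
#'   numerator hypothesis.
#' @param theta_assumed Coancestry coefficient used in the LR probabilities.
#' @param freq_floor Minimum frequency for observed alleles; default
#'   `1/(2n + 1)` for assumed-population sample size `n`.
#' @return A tibble with one row per pair: `pair_id`, `loglr`,
#'   `degenerate`, `n_floored` (count of floored (pair, locus) allele
#'   adjustments).
#' @export
profile_loglr <- function(pairs, panel, assumed_pop, relationship,
                          theta_assumed = 0.01, freq_floor = NULL) {
  kvec <- as_ibd(relationship)
  res <- .profile_engine(
    pairs, panel, assumed_pop, kvec, theta_assumed,
    theta_ci = theta_assumed, freq_floor = freq_floor
  )
  res[c("pair_id", "loglr", "degenerate", "n_floored")]
}

#' Confidence intervals on the profile log likelihood ratio
#'
#' The total \eqn{\ln \hat{LR}} over independent loci is approximately
#' normal by the central limit theorem, with variance obtained by the delta
#' method from the allele-frequency covariance model
#' \eqn{\mathrm{Cov}(\hat p_i, \hat p_j) = c\,(p_i \delta_{ij} - p_i p_j)},
#' \eqn{c = \theta_{CI} + (1-\theta_{CI})/(2n)}, which combines the
#' Dirichlet (evolutionary) and binomial (sampling) components of
#' allele-frequency uncertainty. The two-sided interval is
#' \eqn{\ln\hat{LR} \mp z_{1-\alpha/2}\sqrt{\mathrm{Var}}}; exponentiate to
#' obtain the interval on the LR itself. Pairs with \eqn{\ln LR = -\infty}
#' propagate as a degenerate `(-Inf, -Inf)` interval with `variance = NA`.
#'
#' @inheritParams profile_loglr
#' @param theta_ci Coancestry coefficient of the frequency-uncertainty
#'   model (defaults to `theta_assumed`).
#' @param alpha Significance level in `(0, 1)`; default 0.05.
#' @param one_sided If `TRUE`, a lower one-sided interval using
#'   \eqn{z_{1-\alpha}} (upper bound `Inf`).
#' @return A tibble with columns `pair_id`, `relationship`, `assumed_pop`,
#'   `loglr`, `variance`, `lcl`, `ucl`, `z`, `alpha`, `degenerate`,
#'   `n_floored`. `lcl` is the lower confidence limit used as the
#'   conservative identification statistic.
#' @export
lr_confint <- function(pairs, panel, assumed_pop, relationship,
                       theta_assumed = 0.01, theta_ci = theta_assumed,
                       alpha = 0.05, freq_floor = NULL, one_sided = FALSE) {
  .lr_confint_impl(
    pairs, panel, assumed_pop, relationship, theta_assumed,
    theta_ci, alpha, freq_floor, one_sided
  )
}

.lr_confint_impl <- function(pairs, panel, assumed_pop, relationship,
                             theta_assumed = 0.01, theta_ci = theta_assumed,
                             alpha = 0.05, freq_floor = NULL,
                             one_sided = FALSE, cache = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)", class = "famlr_config_error")
  }
  kvec <- as_ibd(relationship)
  rel_label <- if (is.character(relationship)) {
    .match_relationship(relationship)
  } else {
    paste0("k=(", paste(signif(kvec, 6), collapse = ","), ")")
  }
  res <- .profile_engine(pairs, panel, assumed_pop, kvec, theta_assumed,
    theta_ci, freq_floor,
    cache = cache
  )
  z <- if (one_sided) qnorm(1 - alpha) else qnorm(1 - alpha / 2)
  sdv <- sqrt(res$variance)
  lcl <- res$loglr - z * sdv
  ucl <- if (one_sided) rep(Inf, nrow(res)) else res$loglr + z * sdv
  lcl[res$degenerate] <- -Inf
  ucl[res$degenerate] <- -Inf
  tibble::tibble(
    pair_id = res$pair_id,
    relationship = rel_label,
    assumed_pop = assumed_pop,
    loglr = res$loglr,
    variance = res$variance,
    lcl = lcl,
    ucl = ucl,
    z = z,
    alpha = alpha,
    degenerate = res$degenerate,
    n_floored = res$n_floored
  )
}

#' Monte-Carlo variance of the profile log likelihood ratio
#'
#' Diagnostic sampler for the frequency-uncertainty model underlying
#' [lr_confint()]: for each replicate, population frequencies are drawn from
#' a Dirichlet with concentration \eqn{p (1-\theta_{CI})/\theta_{CI}}, then
#' `2n` alleles are resampled multinomially, and \eqn{\ln LR} is recomputed
#' at the resampled frequencies. The empirical variance over replicates is
#' an independent check on the delta-method variance. This sampler is a
#' diagnostic only; reported confidence intervals never use resampling.
#'
#' @inheritParams lr_confint
#' @param n_rep Number of Monte-Carlo replicates.
#' @return A tibble with `pair_id` and `mc_variance`.
#' @export
lnlr_mc_variance <- function(pairs, panel, assumed_pop, relationship,
                             theta_assumed = 0.01, theta_ci = theta_assumed,
                             freq_floor = NULL, n_rep = 10000) {
  .check_pop(panel, assumed_pop)
  if (theta_ci <= 0) {
    abort("Monte-Carlo variance needs theta_ci > 0", class = "famlr_config_error")
  }
  kvec <- as_ibd(relationship)
  flist <- .freq_list(panel, assumed_pop)
  n <- .panel_size(panel, assumed_pop)
  n_floor <- freq_floor %||% (1 / (2 * n + 1))
  conc <- (1 - theta_ci) / theta_ci

  pids <- unique(pairs$pair_id)
  out <- numeric(length(pids))
  for (q in seq_along(pids)) {
    pp <- pairs[pairs$pair_id == pids[q], ]
    loglrs <- numeric(n_rep)
    # pre-resolve per-locus genotypes
    gl <- lapply(seq_len(nrow(pp)), function(i) {
      p <- flist[[pp$locus[i]]]
      g_labs <- c(pp$a1_1[i], pp$a1_2[i], pp$a2_1[i], pp$a2_2[i])
      novel <- setdiff(unique(g_labs), names(p))
      if (length(novel) > 0) p <- c(p, setNames(rep(0, length(novel)), novel))
      list(
        p = unname(p),
        i1 = sort(match(c(pp$a1_1[i], pp$a1_2[i]), names(p))),
        i2 = sort(match(c(pp$a2_1[i], pp$a2_2[i]), names(p)))
      )
    })
    for (r in seq_len(n_rep)) {
      tot <- 0
      for (li in gl) {
        gam <- rgamma(length(li$p), shape = li$p * conc)
        pstar <- if (sum(gam) > 0) gam / sum(gam) else li$p
        cnt <- as.vector(stats::rmultinom(1, 2 * n, pstar))
        phat <- cnt / (2 * n)
        obs <- unique(c(li$i1, li$i2))
        phat <- floor_frequencies(phat, obs, n_floor)
        den <- .pair_prob_j(li$i1, li$i2, 0L, phat, theta_assumed)
        num <- kvec[1] * den
        if (kvec[2] > 0) num <- num + kvec[2] * .pair_prob_j(li$i1, li$i2, 1L, phat, theta_assumed)
        if (kvec[3] > 0) num <- num + kvec[3] * .pair_prob_j(li$i1, li$i2, 2L, phat, theta_assumed)
        tot <- tot + (log(num) - log(den))
      }
      loglrs[r] <- tot
    }
    out[q] <- var(loglrs)
  }
  tibble::tibble(pair_id = pids, mc_variance = out)
}
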