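#' Run the true-by-assumed population grid
#'
#' For every (true, assumed) population pair: simulates `reps` related and
#' `reps` unrelated genotype pairs from the true population at
#' `theta_true = 0` (independent founder draws plus gene dropping),
#' computes the lower confidence limit (LCL) of \eqn{\ln \hat{LR}} for the
#' tested relationship under the assumed population's frequencies, and
#' summarises each cell with the distinguishability statistic `D`.
#' Diagonal cells use the matching population; off-diagonal cells measure
#' the cost of assuming the wrong frequency distribution.
#'
#' @param panel A [freq_panel()] with at least two populations.
#' @param relationship Relationship tested in the LR numerator (default
#'   `"sibling"`).
#' @param reps Simulated pairs per cell and class (>= 100; default 10000).
#' @param theta_assumed,theta_ci Coancestry coefficients used in the LR and
#'   in the CI variance model.
#' @param alpha CI significance level.
#' @param freq_floor Observed-allele frequency floor; default
#'   `1/(2n + 1)` of the assumed population.
#' @param seed Integer seed; the whole grid is reproducible from it.
#' @param populations Subset of populations to use; default all.
#' @return A `famlr_grid` object with per-cell summaries (`tidy()`), LCL
#'   samples (`lcl_samples()`), run metadata (`glance()`), and plotting via
#'   `autoplot()`.
#' @export
run_population_grid <- function(panel, relationship = "sibling", reps = 10000,
                                theta_assumed = 0.01, theta_ci = theta_assumed,
                                alpha = 0.05, freq_floor = NULL, seed = 1,
                                populations = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  pops <- populations %||% panel$populations
  .check_pop(panel, pops)
  if (length(pops) < 2) {
    abort("grid needs at least two populations", class = "famlr_config_error")
  }
  if (reps < 100) {
    abort("`reps` must be >= 100", class = "famlr_config_error")
  }

  cells <- list()
  lcls <- list()
  withr::with_seed(seed, {
    caches <- lapply(setNames(pops, pops), function(x) new.env(parent = emptyenv()))
    for (tp in pops) {
      for (ap in pops) {
        rel <- simulate_pairs(panel, tp, relationship, reps, theta_true = 0)
        unr <- simulate_pairs(panel, tp, "unrelated", reps, theta_true = 0)
        ci_r <- .lr_confint_impl(rel, panel, ap, relationship,
          theta_assumed, theta_ci, alpha, freq_floor,
          cache = caches[[ap]]
        )
        ci_u <- .lr_confint_impl(unr, panel, ap, relationship,
          theta_assumed, theta_ci, alpha, freq_floor,
          cache = caches[[ap]]
        )
        d <- distinguishability(ci_r$lcl, ci_u$lcl)
        cells[[length(cells) + 1L]] <- tibble::tibble(
          true_pop = tp, assumed_pop = ap,
          D = as.numeric(d),
          n_finite_related = attr(d, "n_finite_related"),
          n_finite_unrelated = attr(d, "n_finite_unrelated"),
          n_degenerate_related = sum(ci_r$degenerate),
          n_degenerate_unrelated = sum(ci_u$degenerate),
          n_floored = sum(ci_r$n_floored) + sum(ci_u$n_floored)
        )
        lcls[[length(lcls) + 1L]] <- tibble::tibble(
          true_pop = tp, assumed_pop = ap,
          role = rep(c("related", "unrelated"), each = reps),
          pair_id = c(ci_r$pair_id, ci_u$pair_id),
          lcl = c(ci_r$lcl, ci_u$lcl)
        )
      }
    }
  })

  structure(
    list(
      cells = dplyr::bind_rows(cells),
      lcl = dplyr::bind_rows(lcls),
      panel = panel,
      meta = list(
        relationship = .match_relationship(relationship),
        reps = reps, theta_assumed = theta_assumed, theta_ci = theta_ci,
        alpha = alpha, freq_floor = freq_floor, seed = seed,
        populations = pops, panel_hash = rlang::hash(panel$freq)
      )
    ),
    class = "famlr_grid"
  )
}

#' @export
print.famlr_grid <- function(x, ...) {
  m <- x$meta
  cat(
    "<famlr_grid> ", m$relationship, " vs unrelated; ",
    length(m$populations), "x", length(m$populations), " populations, ",
    m$reps, " pairs/cell/class\n",
    sep = ""
  )
  cat(
    "  theta_assumed =", m$theta_assumed, " theta_ci =", m$theta_ci,
    " alpha =", m$alpha, " seed =", m$seed, "\n"
  )
  print(d_matrix(x))
  invisible(x)
}

#' @describeIn run_population_grid Per-cell summary tibble (one row per
#'   (true, assumed) pair with `D` and diagnostic counts).
#' @param x A `famlr_grid`.
#' @param ... Unused.
#' @export
tidy.famlr_grid <- function(x, ...) {
  x$cells
}

#' @describeIn run_population_grid One-row run summary.
#' @export
glance.famlr_grid <- function(x, ...) {
  diag <- x$cells$true_pop == x$cells$assumed_pop
  tibble::tibble(
    relationship = x$meta$relationship,
    n_populations = length(x$meta$populations),
    reps = x$meta$reps,
    theta_assumed = x$meta$theta_assumed,
    theta_ci = x$meta$theta_ci,
    alpha = x$meta$alpha,
    seed = x$meta$seed,
    mean_diag_d = mean(x$cells$D[diag], na.rm = TRUE),
    mean_offdiag_d = mean(x$cells$D[!diag], na.rm = TRUE)
  )
}

#' LCL samples of a population grid
#'
#' @param x A `famlr_grid`.
#' @return A tibble with columns `true_pop`, `assumed_pop`, `role`,
#'   `pair_id`, `lcl`.
#' @export
lcl_samples <- function(x) {
  stopifnot(inherits(x, "famlr_grid"))
  x$lcl
}

#' Distinguishability matrix of a grid
#'
#' @param x A `famlr_grid`.
#' @return A tibble, rows = assumed populations, columns = true
#'   populations.
#' @export
d_matrix <- function(x) {
  stopifnot(inherits(x, "famlr_grid"))
  wide <- tidyr::pivot_wider(
    x$cells[c("assumed_pop", "true_pop", "D")],
    names_from = "true_pop", values_from = "D"
  )
  wide[match(x$meta$populations, wide$assumed_pop), ]
}

#' Power/FPR curves for every grid cell
#'
#' @param x A `famlr_grid`.
#' @inheritParams power_fpr_curve
#' @return A tibble with `true_pop`, `assumed_pop`, `threshold`, `power`,
#'   `fpr`.
#' @export
grid_curves <- function(x, thresholds = NULL, n_thresholds = 101) {
  stopifnot(inherits(x, "famlr_grid"))
  x$lcl |>
    tidyr::nest(.by = c("true_pop", "assumed_pop")) |>
    dplyr::mutate(curve = purrr::map(.data$data, function(d) {
      power_fpr_curve(
        d$lcl[d$role == "related"], d$lcl[d$role == "unrelated"],
        thresholds = thresholds, n_thresholds = n_thresholds
      )
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("curve")
}

#' @export
autoplot.famlr_grid <- function(object, ...) {
  cells <- object$cells
  pops <- object$meta$populations
  cells$true_pop <- factor(cells$true_pop, levels = pops)
  cells$assumed_pop <- factor(cells$assumed_pop, levels = rev(pops))
  ggplot2::ggplot(cells, ggplot2::aes(.data$true_pop, .data$assumed_pop)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$D)) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$D)),
      colour = "white"
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "true population", y = "assumed population",
      title = paste0(
        "Distinguishability (", object$meta$relationship,
        " vs unrelated)"
      )
    )
}

#' Density plot of per-cell LCL distributions
#'
#' @param x A `famlr_grid`.
#' @return A ggplot: related and unrelated LCL densities faceted by
#'   (assumed, true) population.
#' @export
plot_lcl_densities <- function(x) {
  stopifnot(inherits(x, "famlr_grid"))
  d <- x$lcl[is.finite(x$lcl$lcl), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$lcl, linetype = .data$role)) +
    ggplot2::geom_density() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$assumed_pop),
      cols = ggplot2::vars(.data$true_pop)
    ) +
    ggplot2::labs(x = "LCL of ln(LR)", y = "density")
}

#' Sweep distinguishability over marker counts, relationships and thetas
#'
#' For every combination of marker count, relationship, true coancestry and
#' assumed coancestry: simulates `reps` related and `reps` unrelated pairs
#' on an equi-frequent panel with the urn-model sampler at `theta_true`,
#' computes LCLs at `theta_assumed`, and records the distinguishability
#' `D`. Parent-offspring rows are emitted with `estimable = FALSE` (its
#' unrelated-pair LR is almost always exactly zero, so the LCL distribution
#' is undefined).
#'
#' @param marker_counts Numbers of loci to simulate.
#' @param alleles_per_locus Alleles per equi-frequent locus (10 for
#'   STR-like, 2 for SNP-like markers).
#' @param relationships Relationship names to test.
#' @param theta_true True coancestry values for the simulation.
#' @param theta_assumed Assumed coancestry values for the LR/CI
#'   calculations.
#' @param reps Pairs per class per combination.
#' @param n Diploid sample size of the synthetic reference sample.
#' @param alpha CI significance level.
#' @param seed Integer seed.
#' @param freq_floor Observed-allele floor, as in [lr_confint()].
#' @return A `famlr_sweep` tibble: `marker_type`, `n_markers`,
#'   `alleles_per_locus`, `relationship`, `theta_true`, `theta_assumed`,
#'   `D`, finite counts and `estimable`.
#' @export
run_parameter_sweep <- function(marker_counts = c(10, 20, 30, 40, 50, 60),
                                alleles_per_locus = 10,
                                relationships = c(
                                  "sibling", "half-sibling",
                                  "first-cousin", "second-cousin"
                                ),
                                theta_true = 0, theta_assumed = 0.01,
                                reps = 2000, n = 200, alpha = 0.05, seed = 1,
                                freq_floor = NULL) {
  combos <- tidyr::expand_grid(
    n_markers = marker_counts,
    relationship = relationships,
    theta_true = theta_true,
    theta_assumed = theta_assumed
  )
  rows <- vector("list", nrow(combos))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(combos))) {
      cb <- combos[i, ]
      rel_name <- .match_relationship(cb$relationship)
      if (rel_name == "parent-offspring") {
        # the unrelated-pair LR is almost always exactly zero, so the LCL
        # distribution (and hence D) is undefined; excluded by policy
        rows[[i]] <- tibble::tibble(
          marker_type = paste0(alleles_per_locus, "-allele"),
          n_markers = cb$n_markers,
          alleles_per_locus = alleles_per_locus,
          relationship = rel_name,
          theta_true = cb$theta_true,
          theta_assumed = cb$theta_assumed,
          D = NA_real_,
          n_finite_related = NA_integer_,
          n_finite_unrelated = NA_integer_,
          estimable = FALSE
        )
        next
      }
      panel <- generate_equifrequent_panel(cb$n_markers, alleles_per_locus, n)
      rel <- simulate_pairs(panel, "pop1", cb$relationship, reps,
        theta_true = cb$theta_true, method = "urn"
      )
      unr <- simulate_pairs(panel, "pop1", "unrelated", reps,
        theta_true = cb$theta_true, method = "urn"
      )
      cache <- new.env(parent = emptyenv())
      ci_r <- .lr_confint_impl(rel, panel, "pop1", cb$relationship,
        cb$theta_assumed, cb$theta_assumed, alpha, freq_floor,
        cache = cache
      )
      ci_u <- .lr_confint_impl(unr, panel, "pop1", cb$relationship,
        cb$theta_assumed, cb$theta_assumed, alpha, freq_floor,
        cache = cache
      )
      d <- distinguishability(ci_r$lcl, ci_u$lcl)
      rows[[i]] <- tibble::tibble(
        marker_type = paste0(alleles_per_locus, "-allele"),
        n_markers = cb$n_markers,
        alleles_per_locus = alleles_per_locus,
        relationship = .match_relationship(cb$relationship),
        theta_true = cb$theta_true,
        theta_assumed = cb$theta_assumed,
        D = as.numeric(d),
        n_finite_related = attr(d, "n_finite_related"),
        n_finite_unrelated = attr(d, "n_finite_unrelated"),
        estimable = !is.na(as.numeric(d))
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "meta") <- list(reps = reps, n = n, alpha = alpha, seed = seed)
  class(out) <- c("famlr_sweep", class(out))
  out
}

#' @export
autoplot.famlr_sweep <- function(object, ...) {
  d <- object[object$estimable, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$n_markers, .data$D,
    colour = .data$relationship
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$marker_type)) +
    ggplot2::labs(x = "number of markers", y = "distinguishability D")
}

.write_atomic <- function(write_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write the numeric report of a population grid
#'
#' Writes, atomically, the distinguishability matrix, pairwise FST matrix,
#' per-population diversity/entropy table, per-cell LCL histograms,
#' power/FPR curves, and a JSON metadata file sufficient to reproduce the
#' run.
#'
#' @param x A `famlr_grid`.
#' @param outdir Output directory (created if needed).
#' @param hist_bins Number of LCL histogram bins per cell.
#' @return The paths written, invisibly.
#' @export
report_grid <- function(x, outdir, hist_bins = 50) {
  stopifnot(inherits(x, "famlr_grid"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    abort(paste0("cannot create output directory: ", outdir),
      class = "famlr_io_error"
    )
  }
  paths <- c(
    d_matrix = file.path(outdir, "d_matrix.tsv"),
    fst_matrix = file.path(outdir, "fst_matrix.tsv"),
    diversity = file.path(outdir, "diversity.tsv"),
    lcl_histograms = file.path(outdir, "lcl_histograms.tsv"),
    curves = file.path(outdir, "power_fpr_curves.tsv"),
    metadata = file.path(outdir, "run_metadata.json")
  )

  .write_atomic(
    function(p) readr::write_tsv(d_matrix(x), p, progress = FALSE),
    paths["d_matrix"]
  )
  .write_atomic(
    function(p) readr::write_tsv(fst_matrix(x$panel), p, progress = FALSE),
    paths["fst_matrix"]
  )
  div <- dplyr::left_join(
    gene_diversity(x$panel),
    dplyr::rename(profile_entropy(x$panel), entropy_bits = "bits"),
    by = c("population", "locus")
  )
  .write_atomic(
    function(p) readr::write_tsv(div, p, progress = FALSE),
    paths["diversity"]
  )

  fin <- x$lcl$lcl[is.finite(x$lcl$lcl)]
  breaks <- seq(min(fin), max(fin), length.out = hist_bins + 1)
  hists <- x$lcl |>
    dplyr::summarise(
      n_degenerate = sum(!is.finite(.data$lcl)),
      counts = list(
        graphics::hist(pmin(pmax(.data$lcl[is.finite(.data$lcl)], breaks[1]),
          breaks[length(breaks)]
        ), breaks = breaks, plot = FALSE)$counts
      ),
      .by = c("true_pop", "assumed_pop", "role")
    ) |>
    dplyr::mutate(
      bin_lo = list(breaks[-length(breaks)]),
      bin_hi = list(breaks[-1])
    ) |>
    tidyr::unnest(c("counts", "bin_lo", "bin_hi")) |>
    dplyr::rename(count = "counts")
  .write_atomic(
    function(p) readr::write_tsv(hists, p, progress = FALSE),
    paths["lcl_histograms"]
  )

  .write_atomic(
    function(p) readr::write_tsv(grid_curves(x), p, progress = FALSE),
    paths["curves"]
  )
  .write_atomic(
    function(p) {
      jsonlite::write_json(x$meta, p, auto_unbox = TRUE, digits = NA)
    },
    paths["metadata"]
  )
  invisible(paths)
}
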