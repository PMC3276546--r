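#' Build an allele-frequency panel
#'
#' A frequency panel holds per-population, per-locus allele-frequency
#' distributions together with the diploid sample size used to estimate
#' them. The allele universe of a locus is the union of alleles observed in
#' any population; alleles absent from a population carry frequency zero.
#' Frequencies of published tables are typically rounded, so per-(population,
#' locus) sums within `sum_tol` of 1 are renormalized to sum exactly to 1;
#' larger deviations are rejected.
#'
#' @param freq A data frame with columns `population`, `locus`, `allele`,
#'   `frequency`, and (if `sizes` is `NULL`) `sample_size`.
#' @param sizes Optional data frame with columns `population` and `n`
#'   (diploid sample size, individuals). If `NULL`, sizes are taken from the
#'   `sample_size` column of `freq`.
#' @param sum_tol Maximum tolerated deviation of a raw per-(population,
#'   locus) frequency sum from 1 before renormalization (default 0.01).
#' @return An object of class `freq_panel`: a list with tibbles `freq`
#'   (completed over the allele universe) and `sizes`, plus the population
#'   and locus orderings as first encountered.
#' @examples
#' tbl <- tibble::tibble(
#'   population = "pop1", locus = "L1", allele = c("a", "b"),
#'   frequency = c(0.6, 0.4), sample_size = 100
#' )
#' freq_panel(tbl)
#' @export
freq_panel <- function(freq, sizes = NULL, sum_tol = 0.01) {
  freq <- tibble::as_tibble(freq)
  need <- c("population", "locus", "allele", "frequency")
  if (is.null(sizes)) need <- c(need, "sample_size")
  miss <- setdiff(need, names(freq))
  if (length(miss) > 0) {
    abort(
      paste0("frequency table is missing column(s): ", paste(miss, collapse = ", ")),
      class = "famlr_format_error"
    )
  }
  freq$population <- as.character(freq$population)
  freq$locus <- as.character(freq$locus)
  freq$allele <- as.character(freq$allele)

  if (is.null(sizes)) {
    sizes <- dplyr::distinct(freq, .data$population, n = .data$sample_size)
  } else {
    sizes <- tibble::as_tibble(sizes)
    if (!all(c("population", "n") %in% names(sizes))) {
      abort("`sizes` must have columns `population` and `n`",
        class = "famlr_format_error"
      )
    }
    sizes <- dplyr::distinct(sizes, population = as.character(.data$population), n = .data$n)
  }
  if (anyDuplicated(sizes$population) > 0) {
    abort("conflicting sample sizes given for a population",
      class = "famlr_validation_error"
    )
  }
  if (any(!is.finite(sizes$n)) || any(sizes$n < 1)) {
    abort("sample sizes must be >= 1", class = "famlr_validation_error")
  }

  if (any(!is.finite(freq$frequency)) || any(freq$frequency < 0)) {
    abort("allele frequencies must be finite and >= 0",
      class = "famlr_validation_error"
    )
  }
  dup <- duplicated(freq[c("population", "locus", "allele")])
  if (any(dup)) {
    abort("duplicated (population, locus, allele) rows in frequency table",
      class = "famlr_validation_error"
    )
  }

  pops <- unique(freq$population)
  locs <- unique(freq$locus)
  universe <- dplyr::distinct(freq, .data$locus, .data$allele)

  full <- tidyr::expand_grid(population = pops, universe)
  full <- dplyr::left_join(
    full, freq[c("population", "locus", "allele", "frequency")],
    by = c("population", "locus", "allele")
  )
  full$frequency[is.na(full$frequency)] <- 0

  sums <- dplyr::summarise(full,
    s = sum(.data$frequency),
    .by = c("population", "locus")
  )
  bad <- dplyr::filter(sums, abs(.data$s - 1) > sum_tol)
  if (nrow(bad) > 0) {
    abort(
      paste0(
        "allele frequencies do not sum to 1 (tolerance ", sum_tol, ") for: ",
        paste(utils::head(paste0(bad$population, "/", bad$locus), 5L), collapse = ", ")
      ),
      class = "famlr_validation_error"
    )
  }
  full <- dplyr::mutate(full,
    frequency = .data$frequency / sum(.data$frequency),
    .by = c("population", "locus")
  )
  full <- dplyr::arrange(full, match(.data$population, pops), match(.data$locus, locs))

  missing_pops <- setdiff(pops, sizes$population)
  if (length(missing_pops) > 0) {
    abort(
      paste0("no sample size for population(s): ", paste(missing_pops, collapse = ", ")),
      class = "famlr_validation_error"
    )
  }
  sizes <- sizes[match(pops, sizes$population), ]

  structure(
    list(
      freq = full,
      sizes = sizes,
      populations = pops,
      loci = locs,
      alleles = universe
    ),
    class = "freq_panel"
  )
}

#' Read an allele-frequency panel from delimited text
#'
#' Reads a long-format table with header
#' `population,locus,allele,frequency,sample_size` and validates it into a
#' [freq_panel()]. The delimiter is guessed from the file extension
#' (`.tsv`/`.tab` for tab, otherwise comma) unless given.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; `NULL` (default) guesses from the extension.
#' @inheritParams freq_panel
#' @return A `freq_panel`.
#' @export
read_freq_panel <- function(path, delim = NULL, sum_tol = 0.01) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "famlr_format_error")
  }
  delim <- delim %||% (if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE
  )
  freq_panel(raw, sum_tol = sum_tol)
}

#' Write a frequency panel as long-format delimited text
#'
#' @param panel A `freq_panel`.
#' @param path Output path; the delimiter is guessed from the extension as in
#'   [read_freq_panel()].
#' @param delim Field delimiter; `NULL` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_freq_panel <- function(panel, path, delim = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  delim <- delim %||% (if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ",")
  readr::write_delim(tibble::as_tibble(panel), path, delim = delim, progress = FALSE)
  invisible(path)
}

#' @export
as_tibble.freq_panel <- function(x, ...) {
  dplyr::left_join(x$freq, dplyr::rename(x$sizes, sample_size = "n"),
    by = "population"
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
print.freq_panel <- function(x, ...) {
  cat(
    "<freq_panel> ", length(x$populations), " population(s), ",
    length(x$loci), " loci\n",
    sep = ""
  )
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  na <- dplyr::summarise(x$alleles, k = dplyr::n(), .by = "locus")$k
  cat("  alleles per locus:", paste(range(na), collapse = "-"), "\n")
  cat(
    "  sample sizes:",
    paste(paste0(x$sizes$population, "=", x$sizes$n), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Panel accessors
#'
#' `panel_populations()` and `panel_loci()` return the population and locus
#' labels in panel order; `panel_sizes()` the per-population diploid sample
#' sizes; `locus_freq()` the allele-frequency vector (over the locus allele
#' universe) of one population at one locus.
#'
#' @param panel A `freq_panel`.
#' @return A character vector, a tibble, or a named numeric vector.
#' @export
panel_populations <- function(panel) {
  stopifnot(inherits(panel, "freq_panel"))
  panel$populations
}

#' @rdname panel_populations
#' @export
panel_loci <- function(panel) {
  stopifnot(inherits(panel, "freq_panel"))
  panel$loci
}

#' @rdname panel_populations
#' @export
panel_sizes <- function(panel) {
  stopifnot(inherits(panel, "freq_panel"))
  panel$sizes
}

#' @rdname panel_populations
#' @param population A population label in the panel.
#' @param locus A locus label in the panel.
#' @export
locus_freq <- function(panel, population, locus) {
  .check_pop(panel, population)
  if (!locus %in% panel$loci) {
    abort(paste0("unknown locus: ", locus), class = "famlr_validation_error")
  }
  f <- panel$freq[panel$freq$population == population & panel$freq$locus == locus, ]
  setNames(f$frequency, f$allele)
}

.check_pop <- function(panel, population) {
  stopifnot(inherits(panel, "freq_panel"))
  bad <- setdiff(population, panel$populations)
  if (length(bad) > 0) {
    abort(paste0("unknown population label: ", paste(bad, collapse = ", ")),
      class = "famlr_validation_error"
    )
  }
  invisible(TRUE)
}

# named list over loci (panel order) of named frequency vectors
.freq_list <- function(panel, population) {
  .check_pop(panel, population)
  f <- panel$freq[panel$freq$population == population, ]
  idx <- split(seq_len(nrow(f)), factor(f$locus, levels = panel$loci))
  lapply(idx, function(i) setNames(f$frequency[i], f$allele[i]))
}

.panel_size <- function(panel, population) {
  .check_pop(panel, population)
  panel$sizes$n[match(population, panel$sizes$population)]
}
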