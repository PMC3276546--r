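# IBD sharing coefficients (k0, k1, k2) for the supported non-inbred
# pairwise relationships.
.rel_table <- list(
  "parent-offspring" = c(k0 = 0, k1 = 1, k2 = 0),
  "sibling" = c(k0 = 1 / 4, k1 = 1 / 2, k2 = 1 / 4),
  "half-sibling" = c(k0 = 1 / 2, k1 = 1 / 2, k2 = 0),
  "first-cousin" = c(k0 = 3 / 4, k1 = 1 / 4, k2 = 0),
  "second-cousin" = c(k0 = 15 / 16, k1 = 1 / 16, k2 = 0),
  "unrelated" = c(k0 = 1, k1 = 0, k2 = 0)
)

.match_relationship <- function(name) {
  x <- gsub("[ _]+", "-", tolower(trimws(name)))
  x <- sub("s$", "", x) # tolerate plurals ("siblings")
  x <- sub("^half-?sib(ling)?$", "half-sibling", x)
  x <- sub("^sib(ling)?$", "sibling", x)
  x <- sub("^parent-?(offspring|child)$", "parent-offspring", x)
  if (!x %in% names(.rel_table)) {
    abort(
      paste0(
        "unknown relationship: '", name, "'. Supported: ",
        paste(names(.rel_table), collapse = ", ")
      ),
      class = "famlr_validation_error"
    )
  }
  x
}

#' IBD sharing coefficients for a named relationship
#'
#' Returns the probabilities `(k0, k1, k2)` that a non-inbred pair with the
#' given relationship shares 0, 1 or 2 alleles identical by descent at an
#' autosomal locus. Names are matched case-insensitively with hyphen,
#' underscore or space separators.
#'
#' @param relationship One of `"parent-offspring"`, `"sibling"`,
#'   `"half-sibling"`, `"first-cousin"`, `"second-cousin"`, `"unrelated"`.
#' @return A named numeric vector `c(k0, k1, k2)`.
#' @examples
#' ibd_coefficients("sibling")
#' ibd_coefficients("Second cousin")
#' @export
ibd_coefficients <- function(relationship) {
  .rel_table[[.match_relationship(relationship)]]
}

# Accept a relationship name or an explicit (k0, k1, k2) triple.
as_ibd <- function(k) {
  if (is.character(k) && length(k) == 1) {
    return(ibd_coefficients(k))
  }
  k <- as.numeric(k)
  if (length(k) != 3 || any(!is.finite(k)) || any(k < 0) ||
    abs(sum(k) - 1) > 1e-12) {
    abort("IBD coefficients must be 3 non-negative values summing to 1",
      class = "famlr_validation_error"
    )
  }
  setNames(k, c("k0", "k1", "k2"))
}

#' Kinship coefficient of a relationship
#'
#' The kinship coefficient \eqn{\psi = k_1/4 + k_2/2} is the probability
#' that one allele sampled from each member of the pair is identical by
#' descent.
#'
#' @param k A relationship name (see [ibd_coefficients()]) or a numeric
#'   `(k0, k1, k2)` triple.
#' @return A probability.
#' @examples
#' kinship("sibling") # 0.25
#' kinship(c(15 / 16, 1 / 16, 0)) # second cousin, 0.015625
#' @export
kinship <- function(k) {
  k <- as_ibd(k)
  unname(k[2] / 4 + k[3] / 2)
}

#' Table of supported relationships
#'
#' @return A tibble with columns `relationship`, `k0`, `k1`, `k2`,
#'   `kinship`.
#' @export
relationships <- function() {
  tibble::tibble(
    relationship = names(.rel_table),
    k0 = vapply(.rel_table, `[[`, 0, 1),
    k1 = vapply(.rel_table, `[[`, 0, 2),
    k2 = vapply(.rel_table, `[[`, 0, 3),
    kinship = vapply(.rel_table, kinship, 0)
  )
}
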