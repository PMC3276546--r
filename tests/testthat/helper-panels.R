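# Small panels built in code for the tests.

toy_panel <- function() {
  freq_panel(tibble::tibble(
    population = "pop1",
    locus = c("L1", "L1", "L2", "L2", "L2"),
    allele = c("a", "b", "a", "b", "c"),
    frequency = c(0.6, 0.4, 0.1, 0.5, 0.4),
    sample_size = 100
  ))
}

# single-locus panel from a named frequency vector
one_locus_panel <- function(p, n = 100, population = "p1", locus = "L1") {
  freq_panel(tibble::tibble(
    population = population, locus = locus,
    allele = names(p), frequency = as.numeric(p), sample_size = n
  ))
}

two_pop_biallelic <- function(pa, pb, n = 100) {
  freq_panel(tibble::tibble(
    population = rep(c("A", "B"), each = 2),
    locus = "L1",
    allele = rep(c("x", "y"), 2),
    frequency = c(pa, 1 - pa, pb, 1 - pb),
    sample_size = n
  ))
}

# canonical unordered key for a genotype-pair tibble row set
canon_state <- function(d) {
  g1 <- paste(pmin(d$a1_1, d$a1_2), pmax(d$a1_1, d$a1_2))
  g2 <- paste(pmin(d$a2_1, d$a2_2), pmax(d$a2_1, d$a2_2))
  paste(pmin(g1, g2), pmax(g1, g2))
}
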