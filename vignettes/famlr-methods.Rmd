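---
title: "Methods: kinship likelihood ratios, confidence intervals and distinguishability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship likelihood ratios, confidence intervals and distinguishability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(famlr)
```

famlr evaluates how well a likelihood-ratio test separates pairs of
genetic relatives from unrelated pairs when genotypes come from unlinked,
multi-allelic autosomal markers and allele frequencies come from finite,
possibly misspecified population samples. This vignette records the model,
the numerical choices, and the design decisions behind the package, and
states what the simulation results do and do not show.

## The genotype-pair model

A pairwise relationship is characterised by IBD sharing probabilities
$(k_0, k_1, k_2)$, the probabilities that the pair shares 0, 1 or 2
alleles identical by descent at an autosomal locus. The supported
non-inbred relationships are parent-offspring $(0, 1, 0)$, full siblings
$(\tfrac14, \tfrac12, \tfrac14)$, half siblings $(\tfrac12, \tfrac12, 0)$,
first cousins $(\tfrac34, \tfrac14, 0)$, second cousins
$(\tfrac{15}{16}, \tfrac{1}{16}, 0)$ and unrelated $(1, 0, 0)$.

The joint probability of the two unordered genotypes $G$ at one locus is
$$P(G \mid k, \theta, p) = \sum_{j=0}^{2} k_j \, P_j(G; \theta, p),$$
where $P_j$ conditions on exactly $j$ shared founder lineages (so $4 - j$
founder alleles in total; an IBD-shared allele is one founder draw copied
to both individuals). Founder alleles follow the sequential Dirichlet
("urn") rule: after $m$ draws of which $m_i$ were allele $i$,
$$P(\text{next} = i) = \frac{m_i \theta + (1-\theta) p_i}{1 + (m-1)\theta}.$$
This is the canonical coancestry-corrected allele model in forensic
genetics; at $\theta = 0$ it reduces to independent draws from $p$ and the
classical Mendelian two-individual probabilities, and for unrelated pairs
at $\theta > 0$ it reproduces the published Balding–Nichols match
probabilities. The implementation sums the urn probabilities over the
latent assignments consistent with the unordered genotypes
(`genotype_pair_prob()`); the test suite checks exchangeability in the two
individuals, marginalisation to single-genotype probabilities, and that
the probabilities sum to one over the full pair-state space for 2–5
alleles, all six relationships and $\theta \in \{0, 0.01, 0.03, 0.1\}$.

The likelihood ratio at a locus is $P(G \mid k, \theta) / P(G \mid
(1,0,0), \theta)$, and under locus independence
$\ln LR = \sum_l \ln LR_l$. A parent-offspring pair sharing no allele at
some locus has $LR = 0$; the degenerate $\ln LR = -\infty$ state is
propagated explicitly (flag `degenerate`), never as a large negative
float.

## Confidence intervals on ln LR

Allele frequencies are estimates. Two sources of variation are combined in
one covariance model for the estimated frequencies:
$$\mathrm{Cov}(\hat p_i, \hat p_j) = c\,(p_i \delta_{ij} - p_i p_j),
\qquad c = \theta_{CI} + \frac{1 - \theta_{CI}}{2n},$$
the Dirichlet (evolutionary divergence) component plus the binomial
component of sampling $2n$ alleles from $n$ individuals. With 13 or more
independent loci the profile $\ln \hat{LR}$ is approximately normal, so
$$\ln\hat{LR} \mp z_{1-\alpha/2}\sqrt{\widehat{\mathrm{Var}}}$$
is the reported interval (`lr_confint()`; a lower one-sided variant uses
$z_{1-\alpha}$). The variance is assembled per locus by the delta method:
the gradient of $\ln LR_l$ in the locus frequency vector is computed by
component-wise central finite differences (step $10^{-6}$, no simplex
renormalisation — the covariance annihilates the all-ones direction, so
off-simplex components do not contribute), and only the at-most-four
observed alleles have non-zero gradient, which keeps the computation
cheap. Resampling is never used for reported intervals: the frequency
uncertainty includes the evolutionary component, which bootstrapping the
genotype data cannot see. A Monte-Carlo sampler of the
Dirichlet-plus-multinomial model (`lnlr_mc_variance()`) exists purely as a
diagnostic and test oracle.

Two measured properties of this first-order interval are worth knowing.
The delta-method variance sits about 10% below the Monte-Carlo variance of
$\ln LR$ (curvature of $\ln LR$ in the frequencies is ignored at first
order), and in consequence the empirical coverage of the nominal 95%
interval, measured by the test suite over 2,000 replicates of the
frequency-estimation model on 13 equi-frequent 10-allele loci, is about
92.8% rather than 95%. Comparative results (distinguishability, power and
false-positive-rate trends) are unaffected, since all cells share the same
interval construction.

## Simulating pairs

Two samplers generate genotype pairs (`simulate_pairs()`):

* **Gene dropping** (`theta_true = 0`): founder alleles are drawn
  independently from the population's frequencies and dropped through the
  relationship's pedigree, one uniformly chosen allele per parent. The
  pedigrees are the standard non-inbred chains (grandparent couple →
  sibling parents → first cousins, and one generation further for second
  cousins). Independent founder draws implicitly set the population's
  coancestry to zero. The realised founder-lineage sharing count is
  tracked per locus for diagnostics (`track_ibd = TRUE`) and never
  influences sampling.
* **Urn sampling** (`theta_true > 0`, or on request): per locus, the IBD
  state $j$ is drawn from $(k_0, k_1, k_2)$ and $4 - j$ founder alleles
  are drawn sequentially by the urn rule, vectorised over pairs through
  the copy-or-fresh decomposition (after $m$ draws, copy a uniformly
  chosen previous draw with probability $m\theta/(1 + (m-1)\theta)$).

The two samplers agree distributionally at $\theta = 0$ (two-sample
chi-square in the tests), and the urn sampler's pair-state frequencies
match the enumerated probabilities. All simulators are driven by one
seeded RNG per call, vectorised over pairs; the same seed and
configuration reproduce output exactly. Parallel substreams are not
implemented — runs are single-threaded and reproducibility comes from
serial order.

What the synthetic panels emulate and what they do not: equi-frequent
panels (`generate_equifrequent_panel()`) give STR-like (10-allele) and
SNP-like (2-allele) markers with maximal per-locus diversity;
`generate_diverged_panels()` derives populations from a base by Dirichlet
draws with concentration $p(1-F)/F$ — deliberately the same
parameterisation as the CI variance model, so one coherent population
model spans simulation and inference. The built-in
`codis_like_fixture()` is a deterministic 5-population, 13-locus panel
with divergences bracketing the range seen among published forensic STR
panels (pairwise Weir–Cockerham FST roughly 0.005–0.08) and one
low-diversity population built by sharpening the base distribution before
the divergence draw. Real STR data differ in ways these panels ignore:
uneven allele ladders, mutation structure, genotyping error, null alleles
and within-population inbreeding are all absent, so passing tests
demonstrate properties of the model under its own assumptions, not
calibration against any real population.

A calibration detail worth recording: with two populations *each* diverged
from the common base by $F$, the pairwise Weir–Cockerham estimator centres
on $F$ itself; with the base used directly as one of the two populations,
only one lineage carries divergence and the estimator centres on $F/2$
(both verified by Monte Carlo in the tests).

## Distinguishability, power and false positives

The separation between the LCL distributions of related and unrelated
pairs is summarised as
$$D = \frac{(m_R - m_U)^2}{s_R^2 + s_U^2},$$
with sample means and unbiased sample variances of the finite LCLs —
analogous to a non-centrality parameter. $-\infty$ LCLs are excluded from
the moments but counted as below every threshold in the power/FPR curves,
where detection uses strict exceedance (ties are non-detections, a
conservative choice). Parent-offspring $D$ against unrelated pairs is not
estimable (almost every unrelated pair has $LR = 0$ somewhere) and is
flagged rather than computed. The default threshold grid is $-\infty$ plus
101 evenly spaced points over the pooled finite LCL range.

## Parameters and defaults

* `theta_assumed` (default 0.01): coancestry used in LR probabilities; a
  conservative forensic-practice value. Configurable independently of
  `theta_ci` (default: equal), which drives the CI variance.
* `alpha` (default 0.05, two-sided $z \approx 1.96$): the interval level.
  The LCL is taken from the two-sided interval; a one-sided mode is
  available.
* `freq_floor` (default $1/(2n+1)$ of the assumed population): minimum
  frequency assigned to observed alleles before LR evaluation.
  Cross-population evaluation necessarily meets alleles absent from the
  assumed sample; flooring keeps likelihoods defined, the remaining
  frequencies are rescaled to sum to one, and every flooring event is
  counted and reported (`n_floored`).
* `reps` (default 10,000 per cell): grid simulation size. The test suite
  runs reduced sizes chosen to keep the full suite in a few minutes while
  leaving comfortable signal margins: 300–400 pairs per cell for fixture
  grids (5 seeds for majority checks), 1,500–2,000 pairs per sweep
  configuration, 50,000 draws for sampler-distribution checks, 10,000
  Monte-Carlo replicates for the variance oracle and 2,000 for coverage.
* Gene diversity uses the plug-in $1 - \sum \hat p^2$; the $2n/(2n-1)$
  correction is a switch (`corrected = TRUE`). The printed 2-decimal
  summaries cannot distinguish the variants.
* FST uses the multi-allele Weir–Cockerham (1984) ratio-of-sums
  combination with within-population heterozygosity at its Hardy–Weinberg
  expectation $2\hat p(1 - \hat p)$, because the package's inputs are
  frequency tables without genotype counts. Negative raw estimates are
  reported as 0 alongside the raw value; a vanishing denominator returns
  an explicit not-estimable flag.
* Panel loading renormalises per-(population, locus) frequency sums that
  deviate from 1 by at most 0.01 (published tables are rounded) and
  rejects larger deviations.

## Observed behaviour of the trends

On equi-frequent panels the package reproduces the expected comparative
results: $D$ falls by roughly two orders of magnitude from siblings to
second cousins at 15 ten-allele loci; $D$ grows with marker count; the
false positive rate at the LCL > 0 threshold with correct frequencies is
far below $\alpha$ (the interval width reflects frequency uncertainty,
not the chance of coincidental sibling-like sharing); and on the fixture
the low-diversity population has both the lowest diagonal $D$ and the
lowest off-diagonal $D$, with $D$ correlating positively with average gene
diversity across diagonal cells and negatively with pairwise FST across
off-diagonal cells.

One trend is resolution-limited: increasing `theta_assumed` measurably
decreases $D$ for SNP-like panels (about 16% from $\theta = 0$ to
$\theta = 0.2$ at 100 loci), but for the sibling test on 15 equi-frequent
10-allele loci the effect is flat within simulation noise up to
$\theta_{assumed} = 0.2$ even at 3,000 pairs per class. With ten equally
common alleles there are no rare alleles for the $\theta$ correction to
reweight differentially, which plausibly removes most of the effect; the
acceptance checks therefore assert the $\theta$ trend on the SNP
configuration.

## Known limitations

* First-order delta-method intervals undercover by roughly two points at
  nominal 95% (measured above); a second-order correction is out of
  scope.
* Only non-inbred pairwise relationships are modelled: no individual
  inbreeding, no three-way joint probabilities, no linked loci or shared
  haplotype segments, no mutation or genotyping error.
* The discrete-population frequency model is itself coarse: admixed
  ancestry and within-group structure are not represented beyond the
  single coancestry parameter.
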