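---
title: "Calling and comparing broad histone-modification domains with broadHMM"
author: "broadHMM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing broad histone-modification domains with broadHMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadHMM)
library(GenomicRanges)
```

## The problem

Repressive histone marks such as H3K27me3 and H3K9me3 do not form sharp
peaks: they cover diffuse domains of many kilobases at modest read density,
so peak callers designed for point-source signals miscall them badly. The
natural questions for such marks are (i) which parts of a genome are inside
a modified domain in one sample, and (ii) which parts differ between two
samples — for example two inbred strains, two sexes, or two cell lines.
broadHMM answers both with an unsupervised probabilistic model over binned
read counts, with no tuning parameters beyond a bin width and a posterior
threshold.

## The count model

Reads are reduced to their start positions (uniquely mapping reads only,
duplicates assumed removed upstream) and counted in fixed windows of
`binSize` = 1000 bp. To protect the emission densities from pile-up
artefacts, each sample's counts are truncated at the sample's genome-wide
0.999 quantile (the upper 0.1 percentile, nearest-rank definition, so the
cap is an observed integer count).

The per-bin count $x_i$ of one sample is modelled as a two-component
mixture

$$P(x \mid \theta) = \alpha f(x, \theta_0) + (1-\alpha) f(x, \theta_1),$$

where each component is a zero-inflated negative binomial (ZINB)

$$f(x, (r, p, \beta)) = \beta I_{x=0} +
  (1-\beta)\frac{\Gamma(r+x)}{\Gamma(r)\,x!}\,p^r(1-p)^x .$$

Component 0 is constrained to the smaller mean and represents unmodified
background; component 1 carries the heavy tail of modified domains. The
fit uses EM with the median-split start: bins at or below the median count
get responsibility 0.9 for component 0 and 0.1 for component 1, and vice
versa above the median, followed by ordinary maximization steps. For the
dispersion there is no closed-form update, so each M-step profiles $p$ out
as $r/(r+\bar{x}_w)$ and maximizes the weighted profile likelihood over
$\log r$ numerically. For runtime the fit uses only one training
chromosome (configurable; by default the largest present, since a
universally valid fixed name does not exist across genomes).

### The zero split and identifiability

A zero count is ambiguous: it can come from the inflation atom or from the
negative binomial itself, and a correct $\beta$ update requires splitting
the zero responsibility accordingly inside each component (a three-way
latent decomposition). While validating the EM we found that the
likelihood constrains only the *total* inflation mass
$\alpha\beta_0 + (1-\alpha)\beta_1$, never its split between components —
an exactly flat ridge in parameter space. broadHMM resolves it by seeding
the split so that inflation belongs to the unmodified component
($\beta_1 = 0$ is an absorbing point of the EM update and stays zero).
This is also the scientifically sensible attribution: a bin inside a
modified domain has reads by definition, whereas unmappable or empty
background produces the excess zeros. With this convention every
parameter, including $\alpha$, becomes identifiable, and simulated
mixtures are recovered to a few percent from $5 \times 10^4$ bins. One
practical consequence: the EM's default relative log-likelihood tolerance
($10^{-6}$) is ample for region calling, where only the component
*densities* matter, but parameter-recovery studies should tighten it (we
use $10^{-9}$ in our own tests) because movement along the weakly
identified $(r_0, \beta_0)$ direction barely changes the likelihood.

## Single-sample segmentation

The two fitted component densities become the *fixed* emission densities
of a two-state hidden Markov model (states unmodified/modified) — fixing
emissions decouples "what do modified counts look like" from "where are
the domains". Baum–Welch re-estimates only the transition matrix and the
initial distribution, pooling expected transition counts across
chromosomes into one shared matrix; each chromosome restarts from the
initial distribution. Transitions start from a 0.9 self-transition prior
to reflect domain persistence (this accelerates convergence but does not
change the fixed point on our test data). The forward–backward algorithm
(scaled, implemented in C++) then yields the per-bin posterior of being
modified, and a bin is called modified when that posterior exceeds
$\lambda = 0.5$ — equivalent to the maximal-probability state in a
two-state model. Consecutive same-state bins merge into regions; regions
always partition the binned genome, so per-state totals in Mb are simple
width sums.

## Two-sample comparison

For samples A and B the hidden state of a bin is the pair $(a, b)$ of
modification indicators, giving four states: both unmodified, both
modified, A-only, B-only. Each state needs a bivariate count distribution
whose margins are the appropriate per-sample ZINB components; closed-form
bivariate count families with arbitrary margins do not exist, so the
margins are coupled with a Gaussian copula. Counts are mapped to normal
scores by the probability integral transform
$z = \Phi^{-1}(F(x))$ (CDF values clipped into
$[10^{-12}, 1-10^{-12}]$ so scores stay finite), and the state's
covariance $\Sigma_{a,b}$ is the sample covariance of these scores over
bins whose *univariate* posteriors support state $a$ in A and $b$ in B
with probability above 0.9. Components with fewer than 50 such bins fall
back to the identity covariance with a warning. Because the transformed
margins are standard normal by construction, $\Sigma_{a,b}$ is rescaled
to a correlation matrix before evaluation (the general
$(\rho, \sigma_x, \sigma_y)$ form is retained in storage and in the
parameter files); the estimated correlation is capped at $|\rho| \le
0.999$ so the matrix stays positive definite even for degenerate supports
such as a sample compared against itself.

Since counts are discrete, the emission probability of a pair $(x, y)$ is
a rectangle probability,

$$P(X = x, Y = y) = \int_{\Phi^{-1}(F_x(x-1))}^{\Phi^{-1}(F_x(x))}
  \int_{\Phi^{-1}(F_y(y-1))}^{\Phi^{-1}(F_y(y))}
  \phi_{\Sigma}(z_x, z_y)\, dz_x\, dz_y,$$

with $F(-1) = 0$ mapping to a $-\infty$ bound. It is evaluated with the
established Genz algorithm for the bivariate normal CDF
(`mvtnorm::pmvnorm`), exact up to CDF accuracy and fast. Two numerical
conventions matter here: probabilities are floored at $10^{-300}$ before
logs so HMM recursions never see $-\infty$, and the two integration
dimensions are put into a canonical order before evaluation, which makes
the density bitwise symmetric under a joint swap of the samples — so
swapping the input samples exchanges A-only and B-only calls exactly.
Emission values are memoized per component: counts are small integers
repeated genome-wide, so each distinct $(x, y)$ pair is computed once.

The four copula components are the fixed emissions of a four-state HMM;
Baum–Welch again estimates only transitions (the high-confidence support
fractions $\gamma_{a,b}$ are kept as a diagnostic, the transition
structure supersedes them), and each bin is classified by its maximal
posterior state. Argmax ties — vanishingly rare with continuous
posteriors — break conservatively in the order both-unmodified,
both-modified, A-only, B-only. Differential regions are the union of the
A-only and B-only states.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `binSize` | 1000 bp | aggregation window; larger bins trade resolution for signal |
| `lambda` | 0.5 | posterior threshold for the modified call (univariate) |
| `confidence` | 0.9 | univariate posterior cutoff for copula covariance supports |
| `truncationQuantile` | 0.999 | genome-wide count cap per sample |
| `trainChrom` | largest | chromosome used for the mixture fit |
| `emMaxIter`, `emTol` | 500, 1e-6 | EM stopping rule (relative log-likelihood change) |
| `bwMaxIter`, `bwTol` | 100, 1e-6 | Baum–Welch stopping rule |
| `minSupport` | 50 bins | minimum covariance support before identity fallback |

The EM and Baum–Welch stopping rules are the package's own choices; both
algorithms have guaranteed non-decreasing log-likelihood, which the test
suite verifies on every run.

## What the simulator emulates — and what it does not

`simulateUnivariate()` and `simulateBivariate()` generate data from the
model's own assumptions: hidden states follow a Markov chain per
chromosome (default self-transition 0.95, matching multi-kilobase
domains), counts follow the state's ZINB, and bivariate dependence is
produced by the copula construction itself — a bivariate normal draw
pushed through $\Phi$ and the ZINB quantile function, which guarantees
exact per-state marginals. The default demo conditions are 2 chromosomes
× 5000 bins of 1000 bp, component means ≈ 2.7 (with $\beta_0 = 0.1$) and
25 counts per bin, and copula correlation 0.5 in the concordant states
and 0 in the discordant ones; these sizes let the full differential
pipeline run in well under a minute. The count quantile function inverts
the ZINB CDF in closed form (zero-inflation shifts the negative binomial
quantile), which is exact and deterministic.

Passing tests on these simulations therefore demonstrate *internal*
correctness — EM, forward–backward, covariance estimation and the
rectangle probabilities all agree with independent oracles and recover
planted truth — but not robustness to everything real ChIP-seq data adds:
mappability and GC bias, copy-number differences, fragment-length
effects, or dependence shapes that a Gaussian copula cannot express.
Truncation mitigates, but does not remove, artefact pile-ups. No input
(IgG) control is used, by design.

## Degenerate inputs and edge cases

* Constant count tracks (e.g. all zero) cannot support a two-component
  fit and raise an error that names the sample.
* Bins impossible under every state (excluded by the emission floor)
  raise an error naming the bin position.
* A state with zero expected occupancy keeps its previous transition row,
  with a warning.
* Ties at the training median go to the lower group; argmax ties decode
  to the lower state index — both deterministic.
* Counts whose CDF saturates in double precision cannot be inverted by
  the quantile function; it raises an error rather than returning an
  arbitrary cap.

## Verified numerical behaviour

The test suite ties every layer to an independent oracle: the ZINB pmf to
a 50-digit log-gamma evaluation, forward–backward posteriors to exhaustive
path enumeration over all $K^T$ paths, rectangle probabilities to a dense
midpoint quadrature and to factorization at $\rho = 0$, marginalization
and normalization of the copula pmf to the analytic margins, EM and
Baum–Welch to parameter recovery on seeded simulations, and the
end-to-end differential caller to planted four-state truth (with exact
label exchange under sample swap, byte-identical re-runs, and an empty
differential set when a sample is compared against itself). The problem
sizes used — $5 \times 10^4$ draws for recovery checks, $10^4$ bins for
the end-to-end demo — were chosen so the whole suite runs in about half a
minute.

## Known limitations

* Two samples only; the copula construction extends to more dimensions in
  principle, but this package does not implement it.
* Emissions are fixed after the mixture fit; if the training chromosome
  is unrepresentative, the segmentation inherits the bias. Choose
  `trainChrom` deliberately for unusual genomes.
* Replicates are handled by summing counts per bin, not by modelling
  replicate variance.
* The Gaussian copula captures monotone dependence only, and the
  correlation is estimated from high-confidence bins, which slightly
  favours the well-separated part of each state.
* Region calls carry no explicit FDR; the posterior threshold $\lambda$
  is the only control.
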