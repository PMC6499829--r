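---
title: "Reconstructing ancestral spatial gene expression on calibrated echinoderm phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral spatial gene expression on calibrated echinoderm phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Echinoderm larvae of several classes build calcitic skeletons from a
dedicated embryonic cell population, the skeletogenic mesenchyme (SM).
Whether these larval skeletogenic cells in ophiuroids, echinoids and
holothuroids descend from a single ancestral cell type — or arose
convergently — can be probed by treating the *spatial expression domain*
of each regulatory gene in the skeletogenic network (`alx1`, `erg`,
`ets1`, `tbrain`, `vegfr`) as a discrete heritable character on the
eleutherozoan phylogeny and asking which domain each ancestor most
probably used.

Character evolution is modelled as a continuous-time Markov (Mk)
process: a character with $k$ states changes along each branch
independently of the rest of the tree, with instantaneous rate matrix
$Q$ whose off-diagonal entries $q_{ij}$ are tied together by a
constraint pattern — *single-rate* (all equal; for a binary character
$q_{01}=q_{10}$), *two-rate* (binary, both free), or all-rates-different
for multistate characters. The transition kernel over a branch of
length $t$ is $P(t) = e^{Qt}$. Tip likelihoods are combined by
Felsenstein's pruning algorithm with per-node rescaling; the root is
closed with a uniform state distribution (1/k), which is the
conventional default for this family of programs and keeps the
single-rate model reversible (stationary frequencies of $Q$ are
available as an option).

Inference is Bayesian. The free rates carry independent uniform priors
(default U(0, 2)) and are sampled by random-scan Metropolis with a
sliding-window proposal reflected at the prior bounds. Branch-length
uncertainty is integrated out by drawing, as part of every proposal, a
chronogram uniformly from a sample of time-calibrated trees. At each
retained iteration the *exact* marginal state distribution at every
target node is computed under the current (tree, rates) by the two-pass
(below/above) algorithm; the reported "posterior probability" (PP) of a
state at a node is the arithmetic mean of these per-iteration marginals.
This Rao-Blackwellised estimator has the same expectation as sampling
node states but lower variance.

Hypotheses about a specific ancestor are compared by *node fixing*: the
partial likelihoods at the node's MRCA are masked to a single state, the
log marginal likelihood of each masked model is estimated by
stepping-stone sampling (power posteriors $L^\beta \pi$ with $\beta$
spaced as quantiles of a Beta(0.4, 1) law, per-stone log-ratio estimates
summed), and the statistic $2\ln BF = 2(\ln ML_{0} - \ln ML_{1})$ is
interpreted on the conventional scale (0–2 negligible, 2–6 positive,
6–10 strong, >10 very strong). The same machinery compares single-rate
against richer rate models.

## Parameters that matter

* **Branch scaling** (`scale_target_mean`, default 0.1): every tree is
  rescaled so its mean branch length is 0.1 before likelihood work.
  Because only the products $q t$ matter, scaling fixes the unit in
  which the rate prior is expressed; U(0, 2) on the scaled tree is a
  mild prior reaching well past the likelihood's support.
* **Rate prior** (`rate_prior`, default U(0, 2)): the sensitivity suite
  re-runs analyses under U(0, 0.2), U(0, 20) and U(0, 200). Narrow
  priors force slow rates and parsimony-like, more confident
  reconstructions; wide priors admit fast rates and flatten node PPs.
* **MCMC schedule** (`mcmc_settings`): the study-scale schedule is
  10,000,000 generations, thinning 1,000, burn-in 2,000,000. The
  package's tests and examples use a desk-scale profile (500,000 / 100 /
  100,000) whose Monte-Carlo error on node PPs is well below 0.01 —
  adequate because the quantities compared are means of smooth
  per-iteration marginals. Proposal windows adapt toward acceptance
  0.2–0.4 during burn-in only, then freeze, so the retained chain is a
  valid fixed-kernel Metropolis sample.
* **Stepping stone** (`ss_settings`): study scale is 1,000 stones of
  100,000 iterations; 100 stones of 10,000 iterations reproduce a
  10,000-point quadrature of the 5-tip oracle problem to ~0.002 log
  units and are the desk default.

## The chronogram sampler and what it does not emulate

The sequence-based divergence-time machinery (alignment, substitution
model, relaxed clock, birth–death prior) is outside this package's
scope. In its place `sample_chronogram()` draws calibration-consistent
node ages directly on the fixed 12-genus topology: each of the seven
fossil-calibrated nodes uniformly inside its hard bounds (truncated by
its parent's age), every uncalibrated node uniformly between the oldest
calibrated minimum among its descendants and its parent's age, in a
root-to-tip pass. The package consumes ages only through branch lengths
rescaled to mean 0.1, so what matters is relative node depth; the
helper `gamma_clock_prior()` reproduces the moment-matching step
(`alpha = (m/s)^2`, `beta = m/s^2`; 0.016 with scale 0.016 gives alpha
1, beta 62.5) used when a real clock analysis is set up. An externally
produced tree sample (one Newick per line, or a NEXUS TREES block) can
be substituted anywhere a sampled set is accepted.

Two features of a real divergence-time posterior are *not* emulated, and
they matter for interior nodes. First, a data-driven posterior
concentrates and correlates node ages; the uniform sampler instead makes
interior stems as short or as long as the calibration windows allow.
Second — and decisively for the asterozoan ancestor — the asterozoan
crown ([477, 521] Ma) and the eleutherozoan root ([481, 521] Ma) windows
overlap almost completely, so every sampled tree separates those two
nodes by a stem that is a fraction of a percent of tree depth after
scaling. Marginal distributions at nodes joined by so short a branch are
mathematically near-identical for any rate the prior supports (we
verified PP differences < 0.01 across two orders of magnitude of the
rate). Reconstructions at the asterozoan MRCA therefore inherit the
root's (typically strong) support instead of showing the near-equivocal
values a BEAST-style posterior can produce there, and comparable
compression affects the vegfr root and echinoid tbrain magnitudes.
Passing tests consequently certify the inference machinery
(likelihoods, marginals, marginal-likelihood estimates, coverage,
calibration) and the strong-signal reconstructions, not the exact PP
magnitudes at age-coupled interior nodes on real chronogram posteriors.

## The example dataset

`echinoderm_dataset()` builds the 12-genus study system: one asteroid
(*Patiria*), two ophiuroids (*Amphipholis* and a placeholder second
genus), two holothuroids (*Holothuria*, *Apostichopus*), and seven
echinoids (a cidaroid, four camarodonts including
*Strongylocentrotus*, and the irregulars *Scaphechinus* and
*Echinocardium*). Character scorings derivable from published
descriptions are fixed: `alx1` SM-specific everywhere but mesodermal in
the asteroid (an asteroid apomorphy); `ets1`/`erg` broadly mesodermal
(SM+NSM) except the asteroid; `vegfr` present in SM in all scored
genera, absent in the asteroid; `tbrain` four-state — SM-specific in
camarodonts, mesodermal in cidaroids and holothuroids, endomesodermal
in the asteroid, unscored in *Amphipholis*. Coverage is 12/12 taxa for
`alx1` and `ets1`, 11 for `tbrain`, 7 for `vegfr`, 6 for `erg`,
matching the published per-gene availability; missing data are handled
by pruning, not ambiguity codes.

Scorings the published text does not pin down are set to the clade-modal
state implied by the reported reconstructions and flagged `assumed` in
the dataset metadata: the second ophiuroid's and the irregulars'
`tbrain` stay mesodermal (the restriction of tbrain to skeletogenic
cells is placed on the camarodont stem), the ophiuroid `erg` stays
broad, and the exact genus membership of the 7-taxon `vegfr` and
6-taxon `erg` sets follows clade representation. Every scoring can be
overridden by supplying a TSV matrix (`matrix_file`), which is the
supported route to exactness if curated per-taxon data are available.

## Synthetic data and what passing tests show

`simulate_character()` draws a root state and propagates it through
each branch's $P(t)$ row — exact endpoint sampling, with internal-node
truth retained. The simulation studies use one sampled chronogram
scaled to mean branch length 0.1 and the binary single-rate model:

* *Parameter recovery*: 100 replicates of 200 pooled characters
  simulated at q = 0.5; the 95% central credible interval covers the
  truth in ≥ 90 replicates (8,000-generation pooled-likelihood chains
  with site-pattern collapsing).
* *Calibration*: 1,000 characters with rates drawn from the U(0, 2)
  analysis prior; the claimed per-state probabilities at all 11
  internal nodes, pooled and binned in tenths, match empirical
  hit frequencies within ±0.1 of each bin centre (bins with ≥ 25
  observations; rates are drawn from the prior because the Bayesian
  PPs are self-consistently calibrated exactly under that draw).

These checks certify the estimator on data generated by its own model;
they cannot certify the scoring of real expression domains or the
adequacy of the Mk model for them.

## Numerical choices

* $P(t)$: closed forms for binary and equal-rates models; Armadillo's
  scaling-and-squaring matrix exponential otherwise. Rows verified to
  sum to 1 within 1e-12; Chapman–Kolmogorov within 1e-10.
* Pruning rescales partials whenever a node's maximum drops below 1e-6,
  accumulating log factors, so likelihoods survive tiny rates.
* The enumeration oracle (`brute_force_loglik` and the test-side
  marginal enumerator) is restricted to ≤ 8 internal nodes.
* The ESS estimator is Geyer's initial-positive-sequence rule on the
  empirical autocorrelations (sum adjacent pairs while positive);
  antithetic chains may legitimately report ESS > n, and a constant
  series reports ESS = n with a degenerate flag.
* Stepping-stone Monte-Carlo error: per-stone delta-method variance of
  the log mean weight, ESS-adjusted, summed across stones.
* Degenerate inputs are errors, not warnings: all-zero branch lengths,
  basal polytomies, duplicate or empty tip labels, unscored tips
  reaching the likelihood, calibration windows that cannot nest.

## Design choices where the design was open

* Trees are drawn uniformly per proposal (the behaviour of the standard
  multi-tree ASR programs); running on a single tree is the degenerate
  case of a one-tree sample, and chains on a repeated-tree sample are
  distributionally identical to single-tree chains (tested by KS).
* Node PPs use per-iteration exact marginals rather than sampled node
  states: same expectation, lower variance.
* Stone powers follow Beta(0.4, 1) quantiles, concentrating effort near
  the prior where the power posterior changes fastest; the shape is
  configurable.
* Problem sizes in the shipped tests: 500 sampled chronograms and the
  desk MCMC profile for the per-gene reconstructions, 50 trees and
  100 × 10,000 stepping stones for the node-fixed tests — sizes at
  which the Monte-Carlo error is an order of magnitude below the
  scientific tolerances being checked.

## Known limitations

* The chronogram sampler reproduces calibration windows, not a
  sequence-informed posterior (see above); interior-node PP magnitudes
  at age-coupled nodes are systematically more confident than a full
  divergence-time analysis would give.
* Characters are analysed independently; correlated evolution between
  genes (shared regulatory events) is out of scope.
* No ascertainment correction is applied: spatial-expression characters
  were collected regardless of variability, so the Mk (not Mkv)
  likelihood is the right one here, but simulated-data studies inherit
  that convention.
* The placeholder genus labels in the fixture mark real sampling
  positions, not biological claims; overriding with a curated matrix is
  the supported path when per-genus scorings are available.
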