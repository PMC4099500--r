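---
title: "Models and methods behind dompop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dompop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dompop` analyses dominant-marker (AFLP-type) band matrices from highly
selfing plant metapopulations. This vignette records the models the
package implements, the numerical choices behind them, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology left room.

## The dominant-marker model under partial selfing

Only band presence/absence is observed; the band-absent ("null")
phenotype arises from the null homozygote plus, under inbreeding, an
excess of homozygosity:

$$P_0(q) = q^2 + F\,q(1-q), \qquad F = \frac{s}{2-s},$$

where $q$ is the null-allele frequency and $s$ the equilibrium selfing
rate. $s$ is an input parameter throughout (default 0.91, typical of a
nearly autogamous orchid), not something the package estimates: mixture
clustering of selfing rates is out of scope.

**Allele-frequency estimation.** For each population-locus cell the
band-absent count is $k \sim \mathrm{Binomial}(n, P_0(q))$ with a
$\mathrm{Beta}(a,b)$ prior on $q$. `estimate_allele_freqs()` returns
the posterior mean by deterministic quadrature rather than an analytic
approximation: 512-node Gauss-Legendre applied after transforming to
the prior-CDF variable $u = \mathrm{pbeta}(q; a, b)$, which absorbs the
prior exactly and keeps the rule accurate even when a fitted prior is
singular at the edges ($a<1$ or $b<1$). Unit tests pin the result to
brute-force Riemann and adaptive-quadrature oracles at $10^{-6}$. The
"fitted" (non-uniform) prior sets $(a, b)$ by method of moments on the
observed null fractions mapped to the allele scale, floored at
$a,b \ge 0.25$ so a degenerate spread can never produce an improper
prior. Posterior means are cached per $(n, F, a, b)$ as a lookup table
over $k = 0..n$, which makes permutation tests and bootstraps cheap.

## Fst: why the ANOVA runs on moment estimates

The among-population variance of *posterior-mean* frequencies is
systematically too small: shrinkage toward the prior mean deflates it,
and a variance-ratio Fst built on it under-recovers a known simulation
target (we measured about 0.07 at truth 0.10 with 20 demes of 20).
`fst_global()` therefore estimates per-locus Fst from *moment*
estimates — the inversion of the observed null-phenotype fraction,
$\hat q = P_0^{-1}(k/n)$ — with the among-population variance corrected
by the delta-method sampling variance of each $\hat q$ and normalised
by $\bar q(1-\bar q)$. This is the Lynch–Milligan route that the
field's standard dominant-marker software takes, and it recovers
island-model targets within the design tolerance (0.095–0.098 at truth
0.10). Bayesian posterior means still drive everything that benefits
from stabilised frequencies: diversity statistics, Nei distances, the
assignment surface and the Bayesian outlier detector. Two consequences
worth knowing:

* per-locus Fst is truncated at zero, so a mean over loci has a small
  positive floor when true differentiation is near zero;
* duplicating every individual leaves the uncorrected ratio unchanged
  but halves the sampling correction, so the estimate drifts slightly
  upward — exact duplication invariance holds only asymptotically.

The permutation test shuffles individuals among populations keeping
sizes, recomputing counts and the full estimator each time; observed
values count into the null set, so $p \ge 1/(n_{perm}+1)$.

## Phi-PT, distances, trees, IBD

`phipt_amova()` is a distance AMOVA on pairwise squared Euclidean
distances between band profiles (for 0/1 rows this equals the Hamming
distance), with the usual $n_0$-weighted variance components;
$\Phi_{PT} = \sigma^2_{AP}/(\sigma^2_{AP}+\sigma^2_{WP})$. A hand-worked
2-population toy pins the full table in the tests, and vegan's
`adonis2` confirms the SS partition independently. Pairwise mode emits
the symmetric $\Phi_{PT}$ and p-value matrices; pairs containing a
population of one are computed with a warning rather than refused.

Nei's standard distance uses the two-allele identities
$J = \overline{q^2 + (1-q)^2}$ averaged over loci before the log — the
classic formulation — on posterior-mean frequencies. PCoA is classical
metric scaling (`cmdscale`), axes ordered by eigenvalue with percent
variance from the positive part of the spectrum. `nj_consensus()`
resamples loci with replacement, rebuilds frequencies and distances per
replicate, and reports (i) the full-data NJ tree midpoint-rooted with
percent bootstrap support on its internal nodes and (ii) the
majority-rule consensus topology; replicates whose distance matrix
contains an undefined entry are dropped and counted. Midpoint rooting
is applied to the full-data tree because a majority-rule consensus has
no branch lengths to root on. NJ tie behaviour follows ape's
deterministic implementation.

`mantel_ibd()` correlates off-diagonal entries and permutes rows and
columns of one matrix for a one-sided p; geographic distances are
great-circle (haversine) kilometres between population centroids.

## The sliding-window Shannon map

`build_grid()` lays a planar grid in an azimuthal-equidistant frame
centred on the sample centroid (origin at the bounding-box lower-left,
offset half a spacing; default 25-km spacing), converts nodes back to
longitude/latitude, and tests membership with great-circle distances
(35-km radius) — the planar frame only places nodes; all geometry that
matters is spherical. `sliding_shannon()` draws a fixed number of
samples (default 5, without replacement; a flag allows replacement)
per window per bootstrap replicate and averages the plug-in binary
entropy $-[p\ln p + (1-p)\ln(1-p)]$ over loci. The fixed-size
resampling is itself the bias control against unequal sampling density;
the estimator is otherwise the plug-in index with $0\ln 0 = 0$.
Windows with fewer members than the draw size yield `NA` by
construction.

## Assignment, exclusion, and dispersal bounds

The assignment likelihood is the product of per-locus band-frequency
Bernoulli terms in log10 units, so the stringency threshold MLD = 1
means "ten times more likely". Frequencies of exactly 0 or 1 are
replaced by $c/(n+1)$ and $1-c/(n+1)$ with $c = 1$ (configurable).
Scoring an individual against its own population always removes it
first (leave-one-out); a singleton home population leaves no data and
is excluded from that individual's candidate set. An exact tie between
the two best candidates leaves the individual unallocated at any MLD.

Exclusion p-values compare the observed likelihood with those of 1000
genotypes simulated from each candidate population; an individual
below 0.001 everywhere is of putative unsampled origin. The power
simulator re-assigns genotypes drawn from each population's estimated
frequencies. Because those genotypes are simulated from the very
frequencies they are scored against, self-assignment is optimistic for
statistically indistinguishable populations — a property of this class
of resimulation test, visible in the tests as ~90% "correct"
assignment between two samples of one panmictic pool at MLD 0, with
non-allocation rising toward 1 as MLD grows.

Dispersal bounds follow founding-event logic: the lower bound counts
distinct ordered source-destination combinations (plus excluded
individuals, who originate outside the sampled set), the upper bound
counts immigrant individuals (plus excluded), both relative to all
unambiguously assigned individuals (allocated + excluded; an
alternative denominator is a flag). Percentages are printed to one
decimal by round-half-even; distances are haversine between population
centroids and directions are initial bearings binned into eight
45-degree sectors.

## The outlier scan

Each comparison contrasts two groups (pooled habitat classes, or a
population pair). Per-locus differentiation uses the same
moment-with-correction two-sample Fst as the global estimator, and
$H_e = 2\bar q(1-\bar q)$.

**Envelope detector (FDIST/MCHEZA style).** The null simulates loci
under a beta (infinite-island) model — ancestral band-allele frequency
uniform on (0.02, 0.98), group frequencies Beta-distributed with
spread set by a target Fst, individuals drawn with the comparison's
inbreeding, dominant phenotypes emitted, and the estimator re-applied —
so the null and the observation share every layer of distortion. The
target is calibrated iteratively until the simulated mean matches the
observed neutral mean, which itself comes from a trimming loop
(provisional outliers at $p<0.05$ removed, mean re-estimated, envelope
rebuilt). A beta model rather than coalescent simulation of 100 demes
is deliberate: at these differentiation levels the two are equivalent
and the beta model is orders of magnitude faster. Empirical upper-tail
probabilities are conditioned on He by quantile-binned strata
(20 bins, merged with a warning when sparse), and Benjamini–Hochberg
control runs within each comparison, never across comparisons. Note a
resolution consequence: with $n_{sim}$ simulated loci in $B$ bins the
smallest achievable p is about $B/n_{sim}$, so the number of loci a
single comparison can flag at FDR 5% is bounded by the simulation
size; the default $n_{sim} = 50000$ resolves BH at 5% for up to ~125
loci per comparison.

**Bayesian detector (BAYESCAN style).** A fixed-dimension spike-and-
slab model replaces reversible jump: group frequencies follow
$\mathrm{Beta}(m_i\theta_{ij}, (1-m_i)\theta_{ij})$ with
$\mathrm{logit}(F_{ij}) = \alpha_i\gamma_i + \beta_j$, slab
$\alpha_i \sim N(0, 2^2)$, prior inclusion odds 1:10, and
$\beta_j \sim N(-1, 1.8^2)$ absorbing genome-wide differentiation. The
likelihood convolves the sampling variance of each frequency estimate
into the deme-level Beta variance by moment matching, so estimation
noise cannot masquerade as differentiation. Sampling is Metropolis-
within-Gibbs with vectorised locus updates and a birth/death toggle
proposing from the slab prior. "Strong evidence" for directional
selection is a posterior inclusion probability of at least 0.91 with a
positive locus effect; flagged loci whose split-chain $\widehat R$
exceeds 1.1 are marked unreliable. A prior-only run (flattened
likelihood) returns the prior inclusion probability 1/11, which the
tests assert.

With only two groups the evidence for any single locus is bounded —
roughly a 2-df contrast against the genome-wide differentiation — so
at a background Fst near 0.1 the posterior ceiling for even a fully
diverged locus sits near BF ~ 100. Pairwise comparisons therefore only
cross the 0.91 threshold for near-fixation contrasts on mid-frequency
loci; modest habitat shifts (e.g. half a logit unit) are genuinely
undetectable at these sample sizes by either detector, and the
power-oriented tests document this honestly rather than relaxing the
thresholds.

**Decision rules.** A locus is a significant outlier if both detectors
flag it in at least one pooled between-habitat comparison, or if the
Bayesian detector flags it in at least one between-habitat pairwise
comparison; it is rejected if it is also flagged in any same-habitat
(control) comparison, and the disqualifying control is reported. A
significant outlier is *replicated* when two of its supporting
between-habitat pairwise comparisons share no population. Both rules
are pure functions of the call set.

## The synthetic-data generator

`simulate_metapopulation()` emulates exactly the statistical structure
the analyses assume: locus-specific ancestral band-allele frequencies
(U-shaped Beta(0.6, 0.6), matching the asymmetric band-frequency
spectra of real AFLP data, clamped to [0.03, 0.97]); deme frequencies
Beta-distributed around them with concentration $1/F_{ST}-1$;
inbreeding implemented as correlated allele draws (identical with
probability $F$) rather than explicit generations of selfing — the two
are equivalent for every estimator in the package, which only sees
$F$; habitat-selected loci as a static $\pm\delta/2$ logit shift on
the ancestral frequency, drawn mid-range (0.35–0.65) so selection acts
on standing variation; first-generation migrants carrying a full
source-deme genotype; independent per-band flips at the scoring error
rate; and replicate samples as duplicated pre-error genotypes flipped
independently, which makes the expected replicate mismatch rate
$2\varepsilon(1-\varepsilon)$.

The study-shaped preset fixes the regime the pipeline is designed for:
38 populations (23 dune, 15 fen) with sizes from 3 to 72 summing to
422 individuals, 451 loci, selfing 0.91, target Fst 0.09, scoring
error 0.024, 40 replicate pairs, coordinates spanning roughly 600 km.

What the generator does **not** emulate — and hence what passing tests
cannot certify about real data: linkage between loci (loci are
independent given deme frequencies), size homoplasy (fragment sizes
are synthetic metadata), isolation by distance (deme frequencies are
exchangeable across space), multi-generation admixture of migrants,
and locus-specific error rates.

## Problem sizes and reproducibility

All stochastic functions take explicit seeds; fixed seeds reproduce
datasets, subsample draws, bootstraps and MCMC bit-exactly. The test
suite exercises the pipeline at deliberately desk-scale sizes chosen to
keep estimates stable yet quick: island recoveries at 10–20 demes of
20 individuals and 150–300 loci, assignment power on the full
study-shaped preset (1000 genotypes x 10 iterations), outlier
calibration over 20 seeded neutral datasets of 4 demes x 100 loci with
50000-locus envelopes, and detector power probes over 10 seeds. These
sizes are the package's validation design; the same functions run
unchanged at larger scales.

## Known limitations

* The selfing rate is an input; mis-specifying $s$ biases $F$ and all
  frequency estimates coherently.
* Pairwise Bayesian scans at small deme sizes have a hard evidence
  ceiling (above); pooled contrasts with many demes per habitat are
  the powered route for subtle, polygenic-scale shifts.
* The envelope's empirical p-values cannot fall below ~$B/n_{sim}$;
  raise `n_sim` when scanning many loci in one comparison.
* Exclusion p-values assume locus independence; strong linkage would
  make them anti-conservative.
* The LDD upper bound counts putative immigrants, which at moderate
  differentiation include false assignments; it is a bound, not an
  estimate.
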