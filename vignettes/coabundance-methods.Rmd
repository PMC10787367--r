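---
title: "Methods: coabundance networks, differential edges, and mediation linkages"
author: "coabnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coabundance networks, differential edges, and mediation linkages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coabnet)
```

## The problem

Longitudinal microbiome intervention studies — here, a design with three
treatment arms (a control, a rumen-microbiota transplantation arm RMT, and
an autoclaved-fluid sham arm RFT) sampled at three days after birth in
twelve calves per arm — ask more of a feature table than per-feature
differential abundance. The questions this package answers, in order of the
analysis:

1. Which pairs of microbial features co-vary (coabundance edges), per
   (arm, day) subgroup?
2. Which edges change strength across subgroups (heterogeneity), and which
   are attributable to a single arm (specificity)?
3. Which individual features, phenotypes and metabolites differ across days
   or arms?
4. Which within-calf microbial *changes* track phenotype and metabolite
   changes, and which of those associations exist only in the focal arm?
5. Can a metabolite statistically mediate a microbe-to-phenotype link?

All inference operates on profiled tables (species relative abundances,
pathway counts, metabolite intensities, phenotypes); profiling itself is out
of scope.

## Compositional correlations: SparCC

Relative abundances are compositions: the closure to 1 induces spurious
negative correlation, so Pearson or Spearman correlations of relative
abundances are biased estimates of how the underlying ("basis") abundances
co-vary. SparCC estimates basis correlations from log-ratio variances
$t_{ij} = \mathrm{var}\,\log(x_i/x_j)$, which are invariant to the closure.
Under a sparsity assumption (most pairs uncorrelated), basis variances
$\omega_i$ solve the linear system formed by row sums of $t$, and

$$ r_{ij} = \frac{\omega_i + \omega_j - t_{ij}}{2\sqrt{\omega_i\,\omega_j}}, $$

clipped to $[-1, 1]$. Strongly correlated pairs violate the sparsity
assumption, so the algorithm iteratively excludes the most strongly
correlated pair (above `exclusion_threshold`, default 0.1) from the system
and re-solves, up to `n_exclusion_rounds` (default 10) times. Counts are
smoothed by drawing fractions from a per-sample Dirichlet posterior
(counts + 1); the reported matrix is the component-wise median over
`n_inner_iterations` (default 20) draws. These defaults follow the
reference algorithm; a deterministic point-estimate mode
(`point_estimate = TRUE`) replaces the Dirichlet draws by
$(\mathrm{counts}+1)/\mathrm{sum}$ for exact testing.

Relative abundances are first converted to predicted read counts by
multiplying by each sample's total sequence count (rounding half to even,
which is deterministic and unbiased); pathway read counts are used
directly.

Degenerate cases: a feature whose solved basis variance is non-positive, or
that ends up excluded from nearly every pair, has its correlations set to
`NA` with a warning rather than silently clamped. Fewer than 4 features or
4 samples is an error — below that the system is not identified.

### Significance

Each of `n_permutations` (default 100) permutations shuffles every
feature's counts across samples independently, destroying all
between-feature dependence while preserving marginals, and recomputes the
full SparCC matrix. Two-sided p-values use the add-one convention

$$ p_{ij} = \frac{1 + \#\{b: |r^{(b)}_{ij}| \ge |r_{ij}|\}}{1 + B}, $$

so $p$ is never 0 and, with $B = 100$, the threshold $p < 0.01$ is met only
by an observed value exceeding *all* permuted values. Edges with $p <
\alpha$ (default 0.01) form a subgroup's network.

The observed and permuted tables are not perfectly exchangeable — a
permuted "sample" mixes counts drawn at different depths — so calibration
is checked empirically: on structure-free simulations (20 features, 50
samples, 10 replicates) the fraction of edges at $p < 0.01$ falls within
binomial tolerance of 0.01 (the acceptance suite asserts this). Note also
that p-values of different pairs within one table share permutation
datasets and are therefore positively dependent; pooled rejection rates
have more than binomial variance across tables.

## Edge heterogeneity: Cochran's Q

Treating each subgroup as one study, each edge's per-subgroup correlations
are Fisher-z transformed, $z = \operatorname{atanh} r$ (after clipping $r$
to $\pm 0.999$), with asymptotic variance $1/(n-3)$ — the standard
correlation meta-analysis model. With weights $w_k = n_k - 3$ and pooled
effect $\bar\theta = \sum w_k z_k / \sum w_k$,

$$ Q = \sum_k w_k (z_k - \bar\theta)^2 \sim \chi^2_{k-1} \text{ under homogeneity.} $$

Subgroups with $n \le 3$ carry no information under this variance model and
are dropped with a warning. The edge universe is the union of edges
significant in at least one subgroup; every subgroup's $r$ is filled in
regardless of its own significance, and Benjamini–Hochberg control at FDR
0.05 runs across all tested edges of one feature kind. Only the fixed-effect
Q test is implemented — no $\tau^2$ estimation — matching the analysis this
package reproduces.

## Arm-specific edges: the IQR fence rule

For a heterogeneous edge, quartiles $Q_1, Q_3$ of the $k$ per-arm effect
sizes are computed by linear interpolation (quantile type 7 — with $k = 3$
values the convention matters: $Q_1$ is the midpoint of the lower pair,
$Q_3$ of the upper pair). Fences sit at $Q_1 - 0.75\,\mathrm{IQR}$ and
$Q_3 + 0.75\,\mathrm{IQR}$. The minimum (if below the low fence) and the
maximum (if above the high fence) are candidate outliers; the edge is
called specific to an arm only when exactly one candidate exists. Ties for
the extreme, two simultaneous candidates, or any missing effect size
produce no call. Raw $r$ (not Fisher-z) enters the rule, matching the rule's
statement in terms of the SparCC coefficient itself.

Worked example: effects $(0.10, 0.12, 0.80)$ give $Q_1 = 0.11$,
$Q_3 = 0.46$, $\mathrm{IQR} = 0.35$, high fence $0.7225$; only $0.80$ lies
outside, so the edge is specific to that arm.

With $k = 3$ the rule has a sharp geometry: writing the sorted effects
$(a, b, c)$, the maximum is an outlier iff $c - b > 3(b - a)$. Detection
therefore requires the focal arm's effect to be separated from the others
by at least three times their spread. A power analysis of this geometry
(sample correlations at $n = 50$ per arm) shows that a same-direction shift
of 0.6–0.8 is assigned in only ~60–73% of replicates, whereas a direction
reversal ($-0.2$ in two arms, $+0.8$ in the focal arm) is assigned in
~85–95%. The synthetic generator therefore plants arm-specific edges as
direction reversals — also the biologically interesting case, an
interaction whose sign flips under intervention — and the recovery test
asserts > 80% assignment with < 5% wrong-arm calls at that planting.
End-to-end (SparCC estimates on simulated counts rather than direct sample
correlations), attenuation of the estimates erodes the gap-ratio condition
and assignment drops to ~80%; the rule, not the estimator, is the limiting
factor.

Specificity can be assessed across arms at one day (the default) or,
symmetrically, across days within one arm.

### Hub scores

Within one arm's specific subnetwork (edges weighted by $|r|$), Kleinberg
hub scores are computed; for an undirected graph these reduce to the
principal eigenvector of the weighted adjacency matrix. Scores are
normalized to a maximum of 1 per connected component (a mechanical
consequence is that every component, however small, contains a node with
score 1 — scores compare nodes within a component, not across components),
and nodes above 0.5 are flagged as hubs. `igraph::eigen_centrality` does
the eigenvector computation; the test suite cross-checks it against a
direct eigendecomposition.

## Differential features

Species and pathway tables are centered-log-ratio transformed,

$$ \mathrm{clr}(x)_i = \log(x_i + \varepsilon) - \tfrac1D\sum_j \log(x_j + \varepsilon), $$

with $\varepsilon$ defaulting to half the smallest nonzero value (standard
compositional practice; the choice matters only for zeros), then
inverse-rank transformed per feature, $\Phi^{-1}((\mathrm{rank} - 0.5)/n)$
with average ranks for ties (Blom's offset available). Because the
inverse-rank step is monotone, every rank-based p-value downstream is
unchanged by it — the suite asserts this — and it serves only to put effect
sizes on a comparable normal scale. Phenotypes are tested untransformed.

Kruskal–Wallis (tie-corrected, $\chi^2_{k-1}$) tests each feature across
days within an arm and across arms within a day; BH runs across features
per axis. Dunn's z tests give post hoc pairwise contrasts from mean-rank
differences with tie-corrected pooled variance; they are reported
unadjusted, with the family-level decision made by the Kruskal FDR.
Incidence contrasts (e.g. diarrhea cases by arm) use Fisher's exact test —
`stats::fisher.test` handles both 2×2 and small r×c tables exactly — and
two-sample contrasts (e.g. later milk production, RMT vs others) use the
Wilcoxon rank-sum test, exact for small untied samples.

A caveat the package inherits from the analysis it implements: the
time-axis Kruskal test treats repeated measures on the same calf as
independent strata.

## Delta associations

Within-calf changes $\Delta = x(\mathrm{day}_b) - x(\mathrm{day}_a)$ are
computed per feature for calves observed at both days (days 15→35 and
15→56). Microbial deltas are taken on CLR values, metabolite deltas on log
intensities, phenotype deltas on raw values; Spearman correlation is
invariant to monotone per-feature transforms, so these choices affect only
the recorded effect sizes, not the screen — except CLR, which is a
per-sample (not per-feature) transform and is therefore stated explicitly
and configurable.

All feature × trait pairs are screened per arm by Spearman correlation on
the arm's shared calves (at least five required). The dual rule
$|\rho| > 0.7$ and $p < 0.01$ flags significant associations (the
p-only variant is available via `r_min = 0`). P-values: for $n \le 9$,
exact by exhaustive enumeration of the $n!$ rank permutations; for larger
untied samples, the exact-null Edgeworth approximation of
`stats::cor.test(exact = TRUE)`; with ties, the t approximation. The
t approximation alone is visibly anticonservative at the study's per-arm
sizes (its true $P(p < 0.01)$ is ≈ 0.013 at $n = 10$, enough to fail a 1%
calibration check), which is why the exact-null route is the default for
untied data.

An association is specific to the focal arm (default RMT) when it is
significant there and, in every other arm, either not significant or of
opposite sign — the latter clause keeps genuinely reversed associations
from being discarded.

## Mediation

Triads (microbe change, metabolite change, phenotype change) are admitted
when the microbe associates with both traits and the metabolite–phenotype
Spearman p is below 0.01. Each triad is fit by two least-squares models
without treatment–mediator interaction,

$$ M = \alpha_1 + aT + \epsilon_1, \qquad Y = \alpha_2 + cT + bM + \epsilon_2, $$

and `n_sims` (default 1000) coefficient vectors are drawn from each fit's
asymptotic multivariate normal (quasi-Bayesian Monte Carlo). Per draw,
$\mathrm{ACME} = a^{(s)}b^{(s)}$, $\mathrm{ADE} = c^{(s)}$, and total
$= \mathrm{ACME} + \mathrm{ADE}$, an exact identity in this model. Point
estimates are draw means; the ACME p-value is the two-sided sign test
$2\min(\#\{>0\}, \#\{<0\})/n_\mathrm{sims}$, floored at $2/n_\mathrm{sims}$.
No multiplicity adjustment is applied to mediation p-values (a BH option
exists but is off by default), and no sensitivity analysis for sequential
ignorability is attempted: with observational deltas these are
*statistical* mediation linkages, screening hypotheses rather than proving
causal paths.

## The synthetic generator

`simulate_counts()` draws, per arm and day, latent basis abundances
$\exp(\mu + \delta_d + \sigma L'\eta)$ with $\eta \sim N(0, I)$, where $R =
L'L$ is the arm's planted correlation matrix, $\mu \sim N(0, 1.5^2)$ sets
feature base log-abundances (a realistic few-decades abundance range),
$\delta_d$ are per-day log-mean drifts and $\sigma$ (`noise_sd`, default 1)
scales biological variation. Sequencing depth is drawn around `depth_mean`
(default $10^5$; sd 10% of the mean) and reads are multinomial in the
basis fractions, so relative-abundance columns sum to 1 exactly. This
log-normal-basis + multinomial-reads model is exactly the generative
assumption under which SparCC is consistent, which is what makes recovery
tests on the generator meaningful. Defaults mirror the emulated design: 3
arms × 3 days × 12 calves; a `dropout` option removes samples to mimic
incomplete collection. Planted matrices that planting makes non-PD are
projected to the nearest PD correlation matrix with a warning.

Arm-specific edges are planted by overriding one pair's correlation in the
focal arm only (`rho_focal`, default planting $+0.8$, vs `rho_other`,
default $-0.2$ — the direction-reversal rationale above). Mediation chains
realize, relative to each calf's day-15 baseline, metabolite log-intensity
changes $a\,\Delta\mathrm{CLR}$ and phenotype changes
$c\,\Delta\mathrm{CLR} + b\,\Delta\log M$ plus `trait_noise_sd` noise;
unchained traits are independent noise. Ground truth (basis matrices,
planted edges, drifts, chain coefficients) is serialized as text with
hexadecimal numeric encoding, so it round-trips losslessly.

What the generator does *not* emulate: taxonomic name structure beyond
MetaPhlAn-style ids for parser testing, overdispersed (non-multinomial)
read sampling, zero inflation beyond what the log-normal basis produces,
and within-calf autocorrelation of the latent basis across days. Passing
recovery tests on this generator therefore demonstrates correctness of the
estimators under their own assumptions, not robustness to every feature of
real sequencing data.

## Problem sizes and numerical choices

The acceptance suite runs each stage at the sizes its question needs:
SparCC recovery at 30 features × 100 samples over 20 replicate seeds,
permutation calibration at 20 × 50 over 10 replicates, heterogeneity
type-I on 500 simulated edges at the study's per-subgroup $n = 12$, IQR
recovery on 20 replicates of per-arm estimates at $n = 50$,
delta-screen calibration on 1,000 null pairs at the study's 10–12 calves
per arm, mediation recovery at $n = 200$ with a 200-replicate null, and a
byte-identity check of two full pipeline runs at a compact demo scale
(12 features; chosen so the whole suite completes in a few minutes).

Other numerical choices: correlations are clipped to $\pm 0.999$ before
`atanh`; permutation p-values use the add-one convention so 0 never
occurs; `round()` half-to-even for count reconstruction; quantile type 7
throughout; all simulations and resampling derive from explicit integer
seeds, and every stage is bit-reproducible given its seed.

## Limitations

* SparCC's sparsity assumption fails on densely correlated communities;
  the exclusion heuristic mitigates but does not remove this.
* At small $n$ and few features (the per-subgroup scale of the emulated
  design) the permutation-null spread of SparCC estimates is wide;
  per-subgroup networks at $n = 12$ have limited power, and only effects
  near $|r| \approx 0.8$ are reliably recovered.
* The IQR fence rule with $k = 3$ needs a 3:1 gap ratio (see above); it is
  conservative by construction, and near-fence configurations produce no
  call rather than a guess.
* Fisher-z variance $1/(n-3)$ is asymptotic; at $n = 12$ the Q test's size
  is adequate (the suite checks it) but not exact.
* Mediation assumes sequential ignorability, linearity and no
  treatment–mediator interaction; results are screening-level evidence.
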