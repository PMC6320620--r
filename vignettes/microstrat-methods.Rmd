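---
title: "Models and methods behind microstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

microstrat stratifies shotgun-metagenome cohorts into enterotypes and links
the strata to functional potential and host phenotypes. This vignette
explains the models, the tunable parameters and their defaults, the
synthetic generator used for validation, and the numerical and design
choices made where more than one reasonable option existed.

## The Dirichlet-multinomial mixture

Community profiles are overdispersed counts: two samples from the same
community type differ far more than multinomial sampling alone allows. The
DMM model captures this by giving component $k$ a Dirichlet distribution
with parameters $\alpha_k \in \mathbb{R}_{>0}^S$ over taxon proportions;
a sample is generated by drawing a component $z \sim \pi$, a composition
$p \sim \mathrm{Dir}(\alpha_z)$, and counts
$x \sim \mathrm{Multinomial}(N, p)$. Integrating $p$ out gives the
Dirichlet-multinomial likelihood used throughout.

`fit_dmm()` runs EM. The E-step sets responsibilities
$r_{ik} \propto \pi_k\,\mathrm{DirMult}(x_i \mid \alpha_k)$; the M-step
updates $\pi$ and maximizes the responsibility-weighted penalized
log-likelihood over $\theta_k = \log \alpha_k$ with bounded L-BFGS
(30 inner iterations per EM step, warm-started — a generalized-EM update
that keeps the objective monotone). Working in log space enforces
positivity; the box $\theta \in [-8, 8]$ keeps the optimizer away from
degenerate collapse.

**Prior and model selection.** Each $\alpha_{kj}$ carries a diffuse
$\mathrm{Gamma}(0.1,\, 0.1)$ prior (the regularization used by the
standard DMM community-typing method). The number of components is chosen
by a Laplace approximation of the model evidence around the posterior
mode $\hat\theta$:

$$\log Z \approx \log L(\hat\theta) + \log p(\hat\theta)
  + \tfrac{d}{2}\log 2\pi - \tfrac12 \log\det(-H),$$

with $d = K \cdot S$ and $H$ the Hessian of the log posterior in
log-parameter space, taken block-diagonal per component with
responsibility weights (the standard approximation for mixtures). The
prior and the Jacobian of the log transform are included, so the criterion
is comparable across $K$; `select_k()` reports it negated ("smaller is
better"). Eigenvalues of $-H$ are floored at $10^{-10}$ before taking the
log-determinant so near-flat directions (e.g. a nearly empty component)
degrade gracefully instead of failing.

Defaults: 5 restarts from k-means on proportion profiles (`nstart = 10`
inside each restart — proportion k-means is cheap and a poor start is the
dominant failure mode), relative log-likelihood tolerance $10^{-6}$,
`max_iter = 1000`.

## PAM, Calinski–Harabasz, and stability

`pam_cluster()` is k-medoids on any dissimilarity. Instances with at most
3000 candidate medoid sets (all $n \le 8$) are solved exhaustively — exact,
deterministic, and cheap at that size; larger instances use greedy BUILD
followed by steepest-descent SWAP accepting only strictly cost-decreasing
exchanges (equal-cost swaps are rejected so termination is guaranteed).
Nearest-medoid ties go to the lowest medoid index. The exact small-$n$ path
exists because single-swap local search can — rarely — stop in a local
optimum, and small instances are where exactness is testable and free.

The PAM protocols run on root-Jensen-Shannon (a metric; plain JSD is
available via `sqrt = FALSE`) or Bray-Curtis dissimilarities and are scored
by the distance-only Calinski–Harabasz index, with sums of squares computed
from pairwise squared distances ($SS = \sum_{i<j} d_{ij}^2 / n$), so no
centroids are ever needed.

`clustering_stability()` clusters the full data once, then re-clusters
without-replacement subsamples at the full-data $k$ and scores agreement
with the full-data labels restricted to the subsample. Consistency is the
matched-agreement fraction under a maximum-overlap one-to-one matching of
cluster ids ("consistency" is not formally defined by the protocol we
follow; Hungarian-style matching is the natural choice and is isolated
behind `match_clusters()`, exhaustive over assignments and exact for the
small $k$ used here). Default sizes are $\approx 71\text{–}100\%$ of $n$
(the 200/220/240/260/280-of-281 protocol, scaled), 10 repeats per size.
Subsample re-clustering fixes $k$ at the full-data value; `reselect = TRUE`
re-selects per subsample.

## SparCC

Relative abundances induce spurious negative correlation; SparCC estimates
correlations of the unobserved absolute ("basis") abundances from
log-ratio variances $t_{ij} = \mathrm{Var}\log(f_i/f_j)$ under the
assumption that most pairs are uncorrelated. Per inner draw, fractions are
sampled from the per-sample Dirichlet posterior (counts + 1); the basis
variances solve $\sum_{j\ne i} t_{ij} \approx (S-2)\omega_i + \sum_j
\omega_j$, and the strongest pair with $|\rho|$ above 0.1 is excluded and
the system re-solved, up to 10 times ("default parameters": 20 inner
draws, threshold 0.1, 10 exclusion iterations — the reference defaults,
all configurable). The estimate is the element-wise median over inner
draws, clamped to $[-1, 1]$. Negative solved variances are clamped to
$10^{-12}$ with a warning naming the taxon.

Pseudo-P values permute each taxon's counts across samples independently
(breaking all inter-taxon association, preserving marginals) and report
the literal proportion of null data sets with $|\rho|$ at least as extreme
— two-sided on $|\rho|$, no +1 correction (a corrected option exists).
Edges pass at pseudo-P strictly below 0.01.

## Reporter scores

KOs occurring in more than six samples are tested by one-tailed Wilcoxon
rank-sum in both directions; the smaller one-tailed P fixes the direction
and is BH-adjusted across tested KOs, clamped to
$[10^{-15}, 1-10^{-15}]$ so $Z = \pm\Phi^{-1}(1 - P_{\mathrm{adj}})$ stays
finite. A module's raw score is $\sum_{ko \in M} Z_{ko} / \sqrt{m}$; the
reported score subtracts the mean and divides by the SD of that aggregate
over 1000 random size-$m$ KO draws, which absorbs cohort-wide shifts in
the Z distribution (taxa-driven differential abundance moves many KOs at
once; the correction asks whether the module stands out among arbitrary
KO sets of its size). Significance is $|score| \ge 1.96$, the two-sided
95% standard-normal quantile. The enterotype contrast defaults to
one-vs-rest per enterotype; a pairwise mode is available.

## Association battery

`permanova_single()` implements the Gower-centered form explicitly:
$G = J(-\tfrac12 D^2)J$, hat matrix from the single-factor design, and
pseudo-$F$ from the trace ratio — on 1-D Euclidean data this equals the
classical one-way ANOVA $F$, which the tests exploit, and the random-data
cross-check against `vegan::adonis2` guards the implementation. The
permutation P uses the $(1 + \text{hits})/(1 + n_{\mathrm{perm}})$
convention (never exactly zero) with 9999 permutations by default;
`n_perm = "exact"` enumerates all label permutations for $n \le 8$ and
reports the literal proportion. BH families: across factors for the
PERMANOVA battery, within each parameter for Spearman matrices, per
analysis elsewhere; chi-square tests drop the Yates correction by default
(a flag restores it). PCA "component scores" are interpreted as variable
loadings (the plausible alternative — correlations with the PC — differs
only by the singular-value scaling and is not what the 0.2 threshold is
calibrated against here); per-sample scores are returned for group
comparisons, computed from one PCA on all samples.

`glm_adjusted()` is OLS of outcome on exposure plus covariates with
complete cases; if the residual Shapiro-Wilk P is $\le 0.05$ the outcome is
Box-Cox transformed ($\lambda$ maximizing the profile log-likelihood on
the grid $-2..2$ step $0.1$; non-positive outcomes shifted with a warning)
and the model refit. Confounder model 1 adjusts for sex, age and BMI
z-score; model 2 additionally for early-life events — the caller supplies
the covariate set, the result records the model id. The overweight
stratification is composed from existing pieces: dichotomize BMI z at 1.04
(the 85th-percentile normal quantile), dichotomize gene richness at a
configurable count, rank-sum compare.

## The synthetic generator

The generator exists so that every stage can be tested against planted
truth. It emulates: mixture-structured compositions (K components, each
dominated by a distinct taxon), fixed per-sample depths (a uniform range
option exercises rarefaction), a gene layer distributing each taxon's
reads over its genes with stable per-gene weights, partial annotation
(35% of genes taxonomically unannotated by default, reflecting the upper
range of annotated-mapping fractions seen in real catalogs; 20% of genes
without KO), planted log-normal basis correlations for the network stage,
module-level KO boosts restricted to one component, and phenotypes with
component-dependent means/probabilities or component-restricted linear
links. It does **not** simulate reads, sequencing error, strain variation,
or compositional zero-inflation beyond what multinomial sampling induces —
so passing recovery tests demonstrate correctness of the estimators under
the assumed generative model, not robustness to real-data artifacts.

The shipped preset (`preset_config("three_enterotype")`) is a
three-community-type school-age gut cohort: $n = 200$, 50 taxa, depth
5000, equal weights, dominant-taxon Dirichlet parameter 15 over a
background of 0.5 (dominant shares around 40%, comparable to real
enterotype drivers), one enriched module per component (multiplier 6 on
its KOs' gene weights) plus three background modules, and an insulin-like
covariate with slope $-2$ on a dietary-fiber covariate in components 1–2
only (noise SD 5). Effect sizes are not dictated by any published cohort;
they were chosen once to be realistic-but-recoverable and are documented
here rather than tuned.

All generators are pure functions of (config, seed): every operation
derives its stream from the root seed and a fixed label via
`split_seed()`, so stages re-run in isolation reproduce their in-pipeline
draws exactly.

## Problem sizes and runtime choices

The recovery suites run at deliberately modest sizes chosen as the
package's own test scale: full-preset DMM selection over $k = 1..6$
(about 10 s), SparCC recovery at $n = 150$, $S = 20$ with $B = 100$
bootstraps, null calibration at $S = 20$, $B = 200$ with 5 inner draws,
and the stability protocol on a 100-sample, 20-taxon preset with 2 DMM
restarts. The rarefaction default in the shipped pipeline config is 5000
reads (synthetic scale); 20 million is the documented real-data default.

## Known limitations

- The Laplace criterion uses block-diagonal responsibility-weighted
  Hessians; for heavily overlapping components the evidence is
  approximate, and selection should be read alongside the stability
  protocol.
- SparCC assumes sparsity of true correlations; dense correlation
  structure biases the basis-variance solution.
- Reporter-score background correction assumes module membership is
  exchangeable with arbitrary KO sets of the same size.
- The low-coverage taxa filter defaults to cohort-wide gene counts; a
  per-group scope (`scope = "any_group"`) is provided because both
  conventions appear in practice, and they can differ at the margin.
- PERMANOVA here is single-factor (the battery loops factors and adjusts
  across them); no sequential/marginal multi-factor decomposition.
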