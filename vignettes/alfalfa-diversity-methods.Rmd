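---
title: "Methods: linking phenotypic diversity to genetic structure in pooled-sample panels"
author: "alfadiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking phenotypic diversity to genetic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`alfadiv` implements an analysis chain for diversity panels of
heterogeneous, outcrossing crops (the motivating case is cultivated
alfalfa, *Medicago sativa*) genotyped as **pooled samples**: each
accession is characterized by continuous allele frequencies in $[0,1]$
estimated from a bulk of many plants, rather than by individual
genotypes. The chain is:

1. spatial adjustment of field-trial phenotypes with a genomic mixed
   model (`fit_spatial_gblup()`, `adjust_phenotype()`);
2. a genomic relationship matrix from pooled frequencies
   (`compute_relationship()`);
3. unsupervised phenotypic structure — PCA, $k$-means with BIC, DAPC
   (`kmeans_bic_scan()`, `run_dapc()`);
4. concordance of genetic and phenotypic distances by a Mantel test
   (`mantel_test()`);
5. all-relevant trait selection for genetic-group membership
   (`boruta_select()`);
6. a per-SNP Nei $F_{ST}$ scan with an empirical neutral null
   (`fst_outlier_scan()`).

A synthetic-data generator (`simulate_*()`) reproduces the statistical
structure these stages assume, together with the ground truth needed for
parameter-recovery tests. Every number quoted below is recomputed by the
test suite or by `scripts/acceptance.R`; none is asserted from memory.

# The synthetic panel

## Group allele frequencies

Group frequencies follow the Balding–Nichols model: for marker $j$ with
ancestral frequency $p_j \sim U(0.05, 0.95)$ and divergence parameter
$F$, each group's frequency is drawn as

$$ q_{gj} \sim \mathrm{Beta}\!\left(p_j\tfrac{1-F}{F},\; (1-p_j)\tfrac{1-F}{F}\right), $$

whose mean is $p_j$ and variance $F\,p_j(1-p_j)$. Defaults emulate the
study conditions: six usable groups, neutral $F = 0.05$, and a small
minority (~2%) of loci drawn with a much larger $F$ to stand in for
divergent selection. Pooled sampling adds one binomial draw of
`pool_chromosomes` = 400 chromosomes (100 autotetraploid plants) per
accession. An optional within-group drift layer (`accession_fst`) draws
each accession's own frequency around its group frequency; it is off by
default but used in recovery experiments where individual-level
relatedness must be identifiable (see below).

One closed form is worth recording because it is easy to get wrong: for
**two** groups, the expected per-marker Nei $F_{ST}$ (defined against
the *pair mean*, Section "FST scan") is not $F$ but

$$ E[F_{ST}] \approx \frac{F}{2-F}, $$

because each group deviates from the *ancestral* frequency with variance
$F p q$, while only half of that variance separates the two groups from
their own midpoint. At $F = 0.05$ this gives $0.0256$; the generator
tests assert this value, verified by simulation.

## Trials, surfaces, phenotypes

`simulate_trial()` builds an augmented design on a rows × columns grid
(default scale 10 × 44 = 440 plots: a handful of checks replicated six
times, a few entries duplicated, the rest unreplicated), with incomplete
blocks as column strips. `simulate_spatial_surface()` is a seeded
mixture of low-frequency sinusoids (wavelengths between one and two
times `length_scale`, default 10 plots) rescaled to a requested
variance — a deterministic, cheap stand-in for a smooth field trend.
`simulate_phenotypes()` then generates

$$ y = \mu + u_{\mathrm{accession}} + s_{\mathrm{plot}} + \varepsilon,
   \qquad u \sim N(0, G\sigma^2_a),\; \varepsilon \sim N(0, \sigma^2_e), $$

recording the breeding values and variance components as truth. The
generator does **not** emulate linkage disequilibrium along
chromosomes, tetraploid dosage genotypes, genotype-by-environment
interaction, or trait-trait residual correlations; passing tests
therefore show that the estimators recover the generating model's
structure, not that real field data satisfy that model.

# Genomic relationship matrix

With $M$ the accession × marker frequency matrix and $\bar p_j$ the
per-marker mean frequency, $Z = M - P$ (each column centered at its
mean) and

$$ G = \frac{ZZ'}{\tfrac{1}{n}\sum_j \bar p_j (1-\bar p_j)} . $$

Centering at the panel mean is the VanRaden-consistent reading for
frequency data and makes every column of $Z$ sum to zero, so $G$ always
has the vector of ones in its null space — the ridge jitter logged by
the REML fitter on such matrices is expected, not a defect. MAF for
frequency data is $\min(\bar p, 1-\bar p)$; imputation replaces missing
cells with the marker mean (leaving marker means unchanged). The scaling
constant defaults to $n = 16$, the value recommended for pooled
autotetraploid panels; `auto_scale = TRUE` instead solves for the $n$
that makes the mean diagonal exactly 1 and reports it, because "diagonal
close to 1" is panel-dependent (panels with extra within-group drift
have larger diagonals at $n = 16$).

# Spatial adjustment

The per-trait, per-trial model is

$$ y = \mu\mathbf{1} + Zu + Ws + \varepsilon,\quad
   u \sim N(0, G\sigma^2_a),\;
   s \sim N(0, S\sigma^2_s),\;
   \varepsilon \sim N(0, I\sigma^2_e), $$

where $W$ is the tensor product of two open-uniform B-spline bases
(cubic by default; a basis with $k$ knots has $k+2$ functions and forms
a partition of unity) evaluated at each plot's row and column. $S$ is
the knot-effect covariance: identity by default, with a separable AR(1)
option (`S_structure = "ar1"`) since independent knot effects are the
smallest defensible structure and the first-order alternative covers
smoother priors.

REML is computed on the dense covariance
$V = \sigma^2_a ZGZ' + \sigma^2_s WSW' + \sigma^2_e I$ with the global
mean profiled out; the three log-variances are optimized by bounded
L-BFGS-B from equal-split moment starting values, and BLUPs of $u$ and
$s$ come from the mixed-model equations at the optimum. On balanced
one-way data with $G = I$ and no spatial term the estimates agree with
the closed-form random-effects ANOVA to better than $10^{-6}$ (tested).
Degenerate inputs (constant $y$) return the boundary fit exactly. AIC is
$-2\ell_R + 2\nu$ with $\nu$ = the number of *variance* parameters (3
with the spatial term, 2 without); fixed effects are not counted — the
choice is recorded here precisely because an AIC for REML fits is
convention-dependent. `select_knots()` minimizes this AIC over a knot
grid, breaking ties toward fewer knots.

Adjustment subtracts only the fitted surface ($y - W\hat s$), keeping
genetic and residual parts; accession means are taken across a trait's
plots and trials first, and standardization (mean 0, sample SD 1,
denominator $n-1$) happens after averaging. Constant traits are dropped
with a warning.

**Recovery conditions.** Identifying $\sigma^2_a$ against
$\sigma^2_e$ requires either replication or individual-level structure
in $G$. With pool-only sampling, accessions within a Balding–Nichols
group differ only by binomial noise, so $G$ is nearly block-constant and
$u$ has as few effective dimensions as there are groups; variance
recovery within a factor of 2 is then unattainable regardless of the
fitter. The recovery experiments therefore use a 440-plot trial with
two replicates per accession and `accession_fst = 0.05`, where the
suite verifies: surface correlation ≥ 0.8 and all three components
within a factor 2 of truth in ≥ 80% of 20 replicates, and
$\hat\sigma^2_s \le 0.05\,\mathrm{var}(y)$ in ≥ 90% of replicates when
the data carry no spatial signal.

# Phenotypic structure

PCA is the singular value decomposition of the centered standardized
trait matrix; axis signs are canonicalized (largest-magnitude loading
positive) so outputs are order- and platform-stable. `kmeans_bic_scan()`
runs $k$-means (20 restarts) on retained PC scores and scores each $k$
with the spherical-Gaussian criterion

$$ \mathrm{BIC}(k) = nd\,\ln\!\frac{WSS_k}{nd} + kd\,\ln n . $$

A property of this criterion worth knowing: splitting a well-separated
Gaussian cluster always reduces $WSS$ by roughly $0.64\,n_c$ in
log-likelihood units (more in small samples, where the split direction
overfits), while the penalty per extra cluster is only $d \ln n$. In low
dimensions the criterion therefore keeps decreasing past the true $k$;
it becomes consistent only when $d$ is large relative to cluster sizes —
which is exactly the regime in which it is used here (retained PC scores
of a multi-trait panel, tens of dimensions). The cluster-number recovery
experiment runs at $d = 20$ with three 20-point clusters separated by
8 SD, where the true $k$ is selected essentially always; users clustering
in 2–5 dimensions should treat the BIC curve's elbow, not its argmin, as
the signal.

DAPC fits the discriminant step as a generalized eigenproblem of the
between-group versus pooled within-group scatter of the retained PC
scores (default retention: smallest number of PCs explaining ≥ 90%
variance). A ridge of `shrinkage × mean(diag(W))` is added to the within
scatter when ill-conditioned (escalated automatically and logged). Axes
are normalized to unit within-group variance, mapped back through the PC
loadings to per-trait contributions, and sign-canonicalized. The
independent cross-check in the test suite is `MASS::lda`: axis scores
agree to $|r| > 0.999$ and eigenvalue shares to $10^{-6}$ on
well-conditioned data.

# Concordance

Genetic distance is plain Euclidean distance between allele-frequency
profiles. Phenotypic distance is Mahalanobis,
$d_{ij} = \sqrt{(Z_i - Z_j)' \hat\Sigma^{-1} (Z_i - Z_j)}$, with
$\hat\Sigma$ optionally shrunk toward the identity:
$\hat\Sigma(s) = (1-s)\hat\Sigma + sI$. Shrinkage is necessary whenever
the trait count approaches the accession count (with 217 traits and 395
accessions the sample covariance is near-singular); the `"auto"` rule is
$s = p/(n+p)$ — zero-cost, monotone in the trait:accession ratio, and
sufficient to keep the Cholesky factorization well-posed. At $s = 0$ the
distance is affine-invariant (tested); at $s = 1$ it reduces to
Euclidean.

`mantel_test()` uses the Spearman correlation of strictly-upper-triangle
entries (average ranks for ties), builds the null by jointly permuting
rows and columns of the second matrix, and reports the one-sided
(greater) p-value with the observed statistic counted into the null:
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + B)$, so $p \ge 0.001$ at 999
permutations. Identical matrices give $r = 1$, $p = 1/(B+1)$ exactly;
under independence the rejection rate at $\alpha = 0.05$ is calibrated
(checked over 500 replicates). The statistic matches `vegan::mantel` to
machine precision in the cross-check test.

# Trait selection

`prefilter_correlated()` removes redundancy before the wrapper: pairs
with $|r| > 0.9$ are processed in a deterministic order (descending
$|r|$, ties by name) and the member with the larger mean absolute
correlation to the remaining traits is dropped, repeating until no pair
offends.

`boruta_select()` is the shadow-feature wrapper: each iteration appends
a shuffled copy of every undecided trait, fits a random forest (`ranger`,
500 trees, out-of-bag permutation importance, single-threaded for
reproducibility), and a trait scores a hit when its importance exceeds
the *maximum* shadow importance. After each iteration, two-sided
binomial tests on hit counts (success probability 0.5) with Bonferroni
correction across currently-undecided traits confirm traits with
significantly many hits and reject traits with significantly few;
whatever is undecided at `max_runs` stays tentative (no rough-fix pass,
since tentative counts are themselves informative). Decisions are sticky
by construction: once confirmed or rejected, a trait leaves the undecided
pool and its shadow is no longer generated. On the benchmark (10
informative + 40 noise traits, $n = 300$, 3 groups) all informative
traits are confirmed and ≥ 95% of noise is rejected within 100
iterations (5 seeds).

# FST scan

For each unordered pair of groups (groups below `min_group_size = 3`
accessions are excluded, and group frequencies are unweighted means of
member accessions' pooled frequencies):

$$ \bar p = \tfrac{p_1+p_2}{2},\quad H_T = 2\bar p(1-\bar p),\quad
   H_S = \tfrac12\left[2p_1(1-p_1) + 2p_2(1-p_2)\right],\quad
   F_{ST} = \frac{H_T - H_S}{H_T}. $$

Numerically the package evaluates $F_{ST}$ through the algebraic
identity $H_T - H_S = (p_1-p_2)^2/2$, which is exact and keeps the
statistic non-negative at machine precision; markers with $H_T = 0$ are
undefined (`NA`) and excluded from p/q computation rather than set to 0.

The empirical null is one marker set — sampled once, seeded, shared by
every comparison (an explicit user list overrides the random sample;
what "putatively neutral" means operationally is the user's call and is
deliberately configurable). Empirical p-values use the +1/+1 counting
rule with ties counted against the marker; q-values are Benjamini–
Hochberg (via `stats::p.adjust`, NAs propagated around it, the number of
tests being the number of defined p-values); outliers are `q < 0.05`
(strict). Annotation intersects outlier positions with gene intervals
(GFF3, 1-based inclusive; `ape::read.gff` + `GenomicRanges`), counting a
hit when the SNP is inside the gene or within 500 bp of either end
(`relation` is reported from the SNP's point of view; in overlap terms
the gap is `window - 1`). BED export converts to 0-based half-open
coordinates.

**Resolution at desk scale.** The empirical p-value cannot go below
$1/(|null|+1)$. With a 2000-marker null and ~2000 tested loci, BH at
$q < 0.05$ calls nothing until ≥ ~21 loci sit at that floor
simultaneously; desk-scale scans are therefore conservative, and the
*ranking* of $F_{ST}$ values carries most of the information (in the
bundled workflow, the top 1% of loci by maximum pairwise $F_{ST}$ are
planted outliers almost exclusively, even when the q-threshold calls
none). A related caveat concerns power simulations: Balding–Nichols
outlier loci at large $F$ have near-arcsine frequency distributions, so
two groups often drift to the *same* side and a substantial fraction of
"outlier" loci realize little differentiation; per-locus sensitivity of
any caller is bounded well below 1 under that generator.

# Problem sizes and orchestration

The test suite and acceptance script run at deliberately modest sizes
chosen to exercise every code path with stable Monte-Carlo margins:
panels of a few hundred accessions and $10^3$–$4 \times 10^3$ markers,
440-plot trials, 20-replicate recovery experiments, 500-replicate
calibration checks. `run_pipeline()` chains the stages from a validated
configuration (unknown keys rejected; per-stage seeds derived from one
global seed as `seed × 100 + stage index`, so any stage can be re-run in
isolation); every output file is recorded with an md5 hash in a JSON run
report, and re-running a configuration reproduces identical hashes.

# Known limitations

- The generator's independence across markers means LD-aware null
  construction cannot be studied with it.
- Pool sampling uses a single binomial draw per accession; within-pool
  relatedness and sequencing-depth noise are not modeled.
- The AR(1) knot-covariance option fixes its correlation parameter
  rather than estimating it.
- The BIC criterion's argmin is only trustworthy in high-dimensional
  score spaces (see above).
- Mahalanobis "auto" shrinkage is a pragmatic rule, not an optimal
  (Ledoit–Wolf-style) estimate; pass a numeric value to override.
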