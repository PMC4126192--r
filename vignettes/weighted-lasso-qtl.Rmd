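---
title: "Probabilistic genotype imputation and the weighted lasso for QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic genotype imputation and the weighted lasso for QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlassoqtl)
```

## The problem

QTL mapping in a biparental population couples a quantitative trait with a
panel of binary markers: in a recombinant inbred line (RIL) panel every line
is (nearly) homozygous, so each marker carries one of the two parental
genotypes, coded 0 and 1. Two practical complications dominate such data.
First, a noticeable fraction of marker genotypes is missing — in the
motivating *Arabidopsis* Bay-0 × Shahdara panel (165 lines × 69 markers on
5 chromosomes) about 10% — and the missingness tends to run along a
chromosome rather than scatter, because genotyping instruments operate
sequentially (missing at random, MAR, rather than completely at random,
MCAR). Second, among the dozens of markers only a handful carry real
effects, so marker selection must be sparse.

`wlassoqtl` implements a two-step answer. Step one imputes each missing
genotype from its flanking markers and attaches a *certainty weight* to
every imputed value. Step two selects markers with a weighted lasso that
downweights observations in proportion to how much they rely on uncertain
imputations at the markers that currently matter. The surrounding
apparatus — baselines (nearest-marker imputation, multiple-regression scan,
ordinary and adaptive lasso), per-marker LRT/LOD scores, and an Ising-chain
simulation harness with ROC evaluation — makes the two-step method
comparable against standard practice.

## The flanking-marker probability model

Write $x_{c,t}^{(i)} \in \{0, 1\}$ for the genotype of line $i$ at position
$t$ (cM) on chromosome $c$, and $\delta_x = +1$ if $x = 1$, $-1$ if
$x = 0$. Meiosis induces an approximately Markov dependence along a
chromosome, so a marker's genotype is modelled given only its two flanking
markers at $t_0 < t < t_1$.

For an interior marker the package uses the bridge of a symmetric two-state
Markov chain in which agreement across a gap of $d$ cM has probability
$\tfrac12\,(1 + e^{-\alpha d})$:

$$
P(x_t = 1 \mid x_0, x_1)
 = \frac{\bigl(1 + \delta_{x_0} e^{-\alpha (t - t_0)}\bigr)
         \bigl(1 + \delta_{x_1} e^{-\alpha (t_1 - t)}\bigr)}
        {2 \bigl(1 + \delta_{x_0}\delta_{x_1} e^{-\alpha (t_1 - t_0)}\bigr)}.
$$

The rate parameter $\alpha \ge 0$ (per cM) plays the role of a
recombination rate: at $\alpha = 0$ the probability is exactly 1 between
two agreeing "1" flanks (no recombination); as $\alpha \to \infty$ it
decays to $\tfrac12$ (flanks carry no information); with disagreeing
flanks it passes through exactly $\tfrac12$ at the interval midpoint and
tends to the linear interpolation $d_\text{right}/(d_\text{left} +
d_\text{right})$ as $\alpha \to 0$. The absolute slope of the curve is
smallest mid-interval, which is the qualitative shape one expects: the
information changes least when both flanks are far away.

A chromosome-edge marker has a single neighbor, and its model is
$$
P(x_t = 1 \mid x_0) = \tfrac12 + \tfrac12\, \delta_{x_0}\, \beta^{\,d},
$$
with $d$ the distance to the neighbor and $\beta \in [0, 1]$ a per-cM
retention base. The exponent is a power, not a product: only that reading
keeps the expression inside $[0,1]$ for realistic estimates (a fitted
$\beta$ near 0.95 is typical for a dense RIL map), and it forces the
effective constraint $\beta \le 1$, so the optimizer works on $[0, 1]$.
One shared $\beta$ serves both chromosome ends.

The two forms are mutually consistent: the interior bridge is exactly the
conditional of the symmetric chain whose one-sided conditional is the edge
model with $\beta = e^{-\alpha}$. That consistency is what lets the
homogeneity-test bootstrap (below) regenerate data from a single
generative chain.

### Estimation

$\alpha$ and $\beta$ are estimated by pseudo maximum likelihood: the sum
of conditional Bernoulli log-probabilities over every usable
(line, marker) term — interior markers with both immediate neighbors
observed, edge markers with their single neighbor observed; any term with
a missing member is skipped (complete-triple analysis). Parental rows, if
present, are excluded by the caller: they are homogeneous by construction
and carry no recombination information. Each 1-D likelihood is unimodal in
practice, so the package brackets the maximum on a coarse grid and
finishes with Brent search (`stats::optimize`, parameter tolerance
$10^{-9}$), explicitly checking the boundary values ($\alpha = 0$,
$\beta \in \{0, 1\}$) so that degenerate data (no observed recombination)
return the boundary exactly.

Two diagnostics accompany the fit. `homogeneity_lrt()` tests one shared
parameter against one per chromosome with
$\mathrm{LRT} = -2[\ell(\hat\alpha_\text{shared}) -
\ell(\hat\alpha_\text{per-chr})]$, referred to $\chi^2_{C-1}$; because the
pseudo likelihood is not a true likelihood this reference is an
approximation, so a parametric bootstrap (data regenerated under the
fitted shared-parameter chain, preserving the observed missingness
pattern, explicit seed required) is available as well. `pearson_gof()`
sums $(x - \hat\pi)^2 / (\hat\pi(1 - \hat\pi))$ over the usable terms;
its degrees of freedom are taken as (number of terms − number of fitted
parameters), a deliberate package convention — other cell-counting
conventions exist and produce different integer df for the same data.

## Imputation and certainty weights

`impute_genotypes()` fills each missing entry with the model probability
given the nearest *observed* flanking markers (the Markov assumption makes
skipping interior missing neighbors the natural generalization when
neighbors are themselves missing): both sides observed → interior model;
one side → edge model; an entirely missing chromosome for a line →
$P = \tfrac12$. The imputed genotype is the rounded probability and its
weight is

$$ w = 2\,\lvert P - \tfrac12 \rvert \in [0, 1], $$

so a coin-flip probability yields weight 0 and a certain one weight 1;
observed genotypes keep weight exactly 1. Exactly $P = \tfrac12$ rounds
down to 0, deterministically — the weight is 0 there, so the choice cannot
influence the weighted selection step, and determinism beats coin flips
for reproducibility. Unrounded probabilities are kept alongside the
rounded genotypes, and every entry carries a provenance flag
(`observed` / `model_imputed` / `edge_imputed` / `fallback`).

The baseline `nearest_marker_impute()` copies the nearest observed
genotype on the same chromosome (ties toward the lower cM position) and
assigns weight 1 everywhere — it carries no notion of uncertainty, which
is precisely what the comparison is about.

## Phenotype adjustment

Raw trait observations are adjusted for nuisance covariates (age, plate,
temperature, … — the list is data-specific and the module is generic) by
ordinary least squares with an intercept; the residuals become the
response of the selection step. Rows with a missing trait are dropped —
with trait missingness well under a few percent this is safe regardless
of its mechanism. Categorical covariates expand to treatment contrasts
with lexicographically ordered levels, which affects coefficients but not
the residuals. `aggregate_to_rils()` maps residuals onto genotype rows
either by repeating each line's genotype row per observation
(`replicate_rows`, the default: it keeps every observation's residual and
is the natural reading of feeding "residuals for every observation" into
the selector) or by averaging to one response per line (`mean_per_ril`).
Both are exposed because the choice is genuinely open; averaging first is
equivalent to the default followed by per-line averaging.

## The weighted lasso

With completed genotypes $x_{ij}$, certainty weights $w_{ij}$ and
residual responses $y_i$, the weighted lasso estimate is the minimizer of

$$
\sum_{i=1}^n
 \frac{\sum_j w_{ij} \lvert\theta_j\rvert}{\sum_j \lvert\theta_j\rvert}
 \Bigl(y_i - \sum_j \theta_j x_{ij}\Bigr)^2
 + \lambda \sum_j \lvert\theta_j\rvert .
$$

The observation weight is a coefficient-weighted average of the entry
weights: observations that rely on uncertain imputations *at markers that
currently matter* are downweighted; an observation whose imputations all
sit at irrelevant markers ($\hat\theta_j = 0$) is not penalized at all;
a row with zero certainty on the whole active set drops out of the
regression; and with all weights 1 the method is exactly the ordinary
lasso. Because $\theta$ appears inside its own weight, the objective is
solved by alternation: initialize with the ordinary lasso (equivalently,
unit observation weights), then repeat — update
$w_i = \sum_j w_{ij}\lvert\hat\theta_j\rvert / \sum_j
\lvert\hat\theta_j\rvert$ (defined as 1 when $\hat\theta = 0$: no
relevance information yet, so no downweighting), re-solve the weighted L1
problem — until the squared Euclidean change of the weight vector falls
below $\varepsilon = 10^{-8}$, typically within a handful of iterations;
`max_iter = 50` guards against the rare oscillating case, which is
flagged with a warning rather than an error so long path sweeps survive
isolated non-convergence. Because the estimator is defined as the
minimizer of the self-weighted objective and the alternation is not
monotone in it, the solution reported for each $\lambda$ is the visited
iterate with the lowest objective value — in the regular, converging case
that is the fixed point itself.

The inner weighted L1 problem is solved by cyclic coordinate descent with
a deterministic cycling order, implemented in C++ with covariance
updating: soft-threshold arguments are formed from the Gram matrix
$X^\top \mathrm{diag}(v) X$ and maintained incrementally, so a full sweep
costs $O(p^2)$ independent of $n$. This matters here because uncentered
0/1 genotype columns are heavily mutually correlated and the naive
residual-updating scheme needs thousands of sweeps on such designs. The
convergence tolerance on the maximum coefficient change is $10^{-7}$
(loosened to $10^{-6}$ inside the large simulation sweeps).

The penalty grid holds 100 log-spaced values from $\lambda_{\max}$ (the
smallest penalty with an all-zero solution, computed from the data) down
to $\lambda_{\max}/1000$; `bic_select()` picks the path point minimizing
$\mathrm{BIC}(\lambda) = \mathrm{RSS}(\lambda)/s^2 + \mathrm{df}(\lambda)
\ln n$, with $\mathrm{df}$ the nonzero-coefficient count and $s^2$ a
$\lambda$-independent variance scale (full-OLS residual variance when
$p < n$, else the squared MAD of $y$). Ties break toward the larger
$\lambda$: sparsity is the point of using BIC here.

### Baselines and scores

`lasso_path()` is the same solver with unit weights;
`adaptive_lasso_path()` applies per-coefficient penalty factors
$1/\lvert\hat\theta^{\mathrm{OLS}}_j\rvert^\gamma$ ($\gamma \in
\{0.5, 1, 2\}$; a zero OLS coefficient pins the parameter at zero, and
$p \ge n$ is refused rather than silently worked around);
`multiple_regression_scan()` fits one full OLS model and sweeps the
coefficient t-test p-values over $[0,1]$ in steps of 0.015 (67 steps,
comparable in resolution to the 100-point lasso path), with no
multiple-testing correction — the sweep itself is the ROC instrument.
`marker_lrt_scores()` reports $(n/2)\log_{10}(\mathrm{RSS}_{-j} /
\mathrm{RSS})$ for each marker of a chosen set — the LOD scale — clipping
values below 0.01 to 0; the set may be the BIC-selected markers or all
markers (both conventions appear in practice, so both are exposed).

## The simulation harness

`sim_scenario()` encodes the study conditions; its defaults *are* the
conditions of the benchmarking design and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `map` | Arabidopsis-shaped map | 69 markers, 5 chromosomes, lengths 91.3/64.6/72.2/69.1/91.2 cM |
| `n_rils` | 165 | lines per replicate |
| `eta` | 0.4 | Ising coupling of the genotype chain at 1 cM |
| `missing_rate` | 0.1 | marginal missingness |
| `eta_mar` | 0.6 | coupling of the MAR missingness chain |
| `n_qtl`, `effects` | 6, ±0.5 alternating | true markers and their effects |
| `sigma2` | 0.5, 1, 2, 3 | residual-variance grid |
| `n_reps` | 50 | replicates per setting |

Genotypes are simulated per chromosome as a stationary two-state chain on
a 1-cM lattice (chromosome lengths rounded to integer cM) with
neighbor-agreement probability $e^{\eta}/(e^{\eta} + e^{-\eta})$ — the
standard 1-D Ising conditional; the exact form is a package choice, since
only the coupling values are conventional — and the observed matrix reads
the lattice off at the map positions rounded to the nearest site.
Chromosomes and lines are independent. MCAR missingness is i.i.d.
Bernoulli; MAR missingness runs the same kind of chain (coupling
`eta_mar`) over the missingness indicators per line and chromosome, with
an external field solved from the two-state stationary equations
(`uniroot`) so the marginal rate is exact — missing entries then cluster
along the chromosome. Traits are additive:
$y_i = \sum_k \text{effect}_k\, x_{i,\text{qtl}_k} + \varepsilon_i$,
$\varepsilon_i \sim N(0, \sigma^2)$. QTLs sit either evenly spaced over
all markers or clustered in the first halves of chromosomes 1 and 2, both
deterministically.

`run_study()` sweeps each method's selection path (the $\lambda$ grid,
fixed from the first replicate and shared by all replicates so that
replicate averaging is pointwise on a common sweep; significance
thresholds for the regression scan), records TP/FP/TN/FN against the true
QTLs at every sweep point, averages TPR and FPR pointwise over
replicates, and summarizes each averaged ROC curve by its trapezoidal AUC
(anchored at (0,0) and (1,1)). Method labels follow the benchmarking
convention: `model1` = model imputation + weighted lasso, `model2` =
model imputation + regression scan, `model3`/`model4` the nearest-marker
counterparts, plus `lasso` and `alasso_γ` on the model-imputed rounded
genotypes with the weights ignored.

### What the generator does and does not emulate

The generator reproduces the structure that drives the methodology —
binary Markov genotypes with map-scaled dependence, realistic marginal
missingness of both mechanisms, additive sparse trait architecture. It
does not emulate genotyping error, segregation distortion (marginals are
exactly ½), heterozygous residues in an F8 panel, dominance or epistasis,
or trait-dependent missingness. Passing benchmarks therefore support the
methodology under Markov-generated binary genotypes, not under every
failure mode of real genotyping. One consequence of the conventional
coupling $\eta = 0.4$ at 1 cM deserves emphasis: markers ~6 cM apart are
then nearly independent (neighbor correlation $0.38^6 \approx 0.003$), so
imputation is close to uninformative and the weighted lasso's advantage
over the plain lasso shrinks toward Monte-Carlo noise; its advantage over
the adaptive-lasso variants and the advantage of model-based over
nearest-marker imputation remain visible at modest replicate counts. Real
RIL panels are far more strongly linked (a fitted $\alpha$ of order
0.005/cM), where the certainty weights are highly informative.

## Numerical choices and degenerate inputs

* Interior probabilities are computed with `expm1` so that tiny
  $\alpha d$ does not lose precision; the $0/0$ case (disagreeing flanks
  at $\alpha = 0$) returns its analytic limit.
* Zero-weight columns and infinite penalty factors are pinned at zero
  inside the coordinate solver rather than producing NaNs.
* An all-zero response yields a valid all-zero path; an all-missing
  genotype matrix is an estimation error; a fully missing chromosome for
  one line is a documented fallback (probability ½, weight 0, genotype 0).
* Every randomized operation takes an explicit seed; fixed seed implies
  bit-identical output, including whole simulation studies.

## Scale of the shipped checks

The package's own test suite runs the benchmarking studies at reduced
scale, chosen so that the orderings under test are resolvable: 20
replicates at $\sigma^2 = 1$ for the imputation and selector comparisons,
12 replicates for the $\sigma^2$ ladder, and 165 × 69 parameter-recovery
fits at 20 datasets per $\alpha$. The package defaults remain the full
design (50 replicates, full $\sigma^2$ grid).

## Limitations

* Binary genotypes only: heterozygotes, multi-allelic markers and
  physical (bp) coordinates are out of scope, as are VCF/PLINK inputs.
* The imputation is single-draw likelihood-based; multiple imputation is
  deliberately not provided.
* The homogeneity LRT's $\chi^2_{C-1}$ reference is an approximation to a
  weighted-$\chi^2_1$ mixture; use the bootstrap p-value when it matters.
* No epistatic terms, no cross-validated $\lambda$, no confidence
  intervals on the selected coefficients.
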