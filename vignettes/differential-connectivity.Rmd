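---
title: "Differential connectivity analysis: methods and design notes"
author: "diffconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential connectivity analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffconn)
```

This vignette is the package's own account of the method it implements: the
model and its assumptions, the parameters that matter, what the synthetic
generators emulate, the numerical choices, and the limits of what the test
suite demonstrates.

## The statistic

Two samples-by-features matrices $X_1$ ($n_1 \times p$) and $X_2$
($n_2 \times p$) are measured under two conditions. For each group an
association matrix $A$ is built whose entries $a_{ij}$ are either a
correlation coefficient (Pearson or Spearman) or the mutual information
between features $i$ and $j$. The weighted connectivity of feature $i$ is

$$\chi_i = \sum_{j \neq i} |a_{ij}|,$$

and the differential connectivity between the groups is
$\Delta\chi_i = \chi_i^{G1} - \chi_i^{G2}$. For a binary adjacency matrix
$\chi_i$ is the node degree; for correlation weights it lies in
$[0, p-1]$; for MI weights it is unbounded above.

The sum runs over $j \neq i$, never over the diagonal: a correlation
self-weight of 1 (or an MI self-weight of $H_i$) would add a constant to
every node and carry no between-group information. With this convention the
toy two-condition example — a node with 6 edges in condition 1 and 2 in
condition 2 — gives $\Delta\chi = 4$ exactly.

### Hypotheses and the permutation null

The test addresses $H_0: \Delta\chi_i = 0$ against a magnitude alternative.
Each replicate independently permutes every column of both matrices. This
preserves each feature's marginal distribution exactly (means, variances,
and all quantiles) while destroying between-feature association, so the
permuted connectivity has expectation zero and the permuted
$\Delta\chi_i^{perm}$ values form the null distribution $D_i$. The p-value
is

$$P_i = \frac{1 + \#\{|D_i| > |\Delta\chi_i|\}}{N_{perm}},$$

clipped to 1. Choices worth making explicit:

* **Two-sided magnitude comparison.** $\Delta\chi$ can take either sign
  (swapping the groups negates it), so the exceedance count compares
  absolute values. Ties count as non-exceeding.
* **Denominator $N_{perm}$.** The add-one numerator keeps the smallest
  attainable p-value at $1/N_{perm}$ and avoids literal zeros; with the
  plain $N_{perm}$ denominator the decision rule $P_i < \alpha$ is very
  slightly conservative (at $N_{perm} = 200$, $\alpha = 0.05$ the effective
  level is $9/200 = 0.045$). The simulated type-I error therefore sits just
  below the nominal level, well inside the $0.05 \pm 0.02$ band the
  acceptance suite checks.
* **Both groups are permuted** in every replicate, mirroring the pipeline's
  symmetric treatment of the two conditions.
* **No multiple-testing correction by default**; the reported operating
  characteristics are per-feature counts at raw $\alpha$.
  Benjamini–Hochberg adjustment of the significance flag is available via
  `p_adjust = "BH"`.

Under the global null the p-values are approximately uniform (the suite
checks a Kolmogorov–Smirnov distance below 0.1 pooled over features and
replicates), and the test is calibrated independently of sample size.

## Association measures

Pearson and Spearman correlation are delegated to `stats::cor`; Spearman is
computed as Pearson on average ranks, which the permutation loop exploits
(ranking once, then permuting ranks). Correlation-based results are
invariant under positive affine (Pearson) or strictly monotone (Spearman)
transformations of individual features.

Mutual information is computed on discretized data as
$MI = H(X) + H(Y) - H(X, Y)$, with the same entropy estimator applied to
both marginals and the joint table, all on a shared binning.

### Discretization

Continuous variables are binned before estimation. The default is
equal-frequency binning with $\lceil n^{1/3} \rceil$ bins, the conventional
default for this estimation task; both the bin count and an equal-width
scheme are configurable. Equal-frequency binning is rank based: distinct
values yield occupancies differing by at most one, tied values always share
a bin, and a constant variable occupies a single bin (entropy 0). Because
binning depends only on ranks, permuting a column and then binning equals
binning and then permuting the labels — the permutation loop therefore
discretizes once per group and shuffles labels, and caches the marginal
entropies, which are permutation invariant.

### Entropy estimators

For a table of counts $c_x$ over $m$ cells with $n = \sum c_x$:

* **empirical**: $-\sum_{c_x > 0} \frac{c_x}{n}\ln\frac{c_x}{n}$; biased
  downward, bounded by $\ln(\text{occupied bins})$.
* **Miller–Madow**: empirical plus $(|x| - 1)/(2n)$ with $|x|$ the number
  of occupied bins — the first-order bias correction, changing nothing
  else.
* **shrinkage**: plug-in entropy of the James–Stein-shrunken frequencies
  $\hat p_\lambda = \lambda/m + (1-\lambda)c_x/n$ with closed-form
  intensity $\lambda^* = (1 - \sum \hat p^2)\big/\big((n-1)\sum(1/m - \hat
  p)^2\big)$ clipped to $[0, 1]$; a degenerate denominator (uniform
  $\hat p$, or $n < 2$) gives $\lambda^* = 1$. The uniform target runs over
  the full table support, empty cells included.
* **Schurmann–Grassberger**: Bayesian estimator under a symmetric Dirichlet
  prior with per-cell weight $N$ (default $1/m$),
  $\hat H = \frac{1}{n + mN}\sum_x (c_x + N)\,[\psi(n + mN + 1) -
  \psi(c_x + N + 1)]$ with $\psi$ the digamma function. Published variants
  of this estimator differ in the digamma offsets; this package implements
  the form above verbatim and exposes `prior_N`.

Empirical MI is nonnegative and satisfies $MI(x, x) = H(x)$ under shared
binning; the corrected estimators may return slightly negative MI for
near-independent pairs, which the connectivity sum handles through the
absolute value. A worked three-bin example — probabilities
$(0.2, 0.7, 0.1)$, entropy $0.8018$ nats — anchors the empirical estimator
in the tests; all MI values are in nats throughout.

Constant features never abort a computation: they receive zero weight
against all partners, with a warning. This matters because permutation
replicates of near-constant real-world features must not crash a run.

## Synthetic data generators

The generators define the simulation conditions under which the test's
type-I error and power are studied. They emulate three things real
metabolomic data is believed to exhibit: smoothly decaying correlation
neighbourhoods, hub-dominated modules, and heterogeneous average
correlation; plus, through the kinetic sampler, nonlinear cross-sectional
dependence that no Gaussian model reproduces.

### Structured correlation models

All Gaussian data are drawn as $X \sim N(0, \Sigma_p)$ with unit variances
(`MASS::mvrnorm`), so $\Sigma$ is the correlation matrix.

* **Toeplitz/AR(1)**: $\Sigma_{ij} = \rho^{|i-j|}$, positive definite for
  $0 \le \rho < 1$; entries are exact to machine precision.
* **Hub**: groups of sizes $(15, 5)$ by default, each with a hub feature
  whose correlation with member $i = 2, \dots, g$ attenuates as
  $\rho - ((i-2)/(g-2))^\gamma (\rho - \rho_{min})$, quadratic
  ($\gamma = 2$) by default with $\rho_{min} = 0$; non-hub pairs within a
  group and all cross-group pairs are uncorrelated. The raw star-shaped
  structure is indefinite when $\rho\sqrt{\sum_i r_i^2} \gtrsim 1$ (with
  the default 15-member group this happens already near $\rho \approx
  0.37$); the constructor then clips eigenvalues at $10^{-8}$ and
  renormalises to unit diagonal, always with a warning, and keeps the raw
  matrix alongside for inspection.
* **Hardin perturbation**: off-diagonal noise $\epsilon\, u_i^\top u_j$
  from random unit vectors in `edim` dimensions (defaults
  $\epsilon = 0.01$, `edim = 2`), leaving the diagonal at exactly 1 and
  shifting the spectrum by at most $\epsilon$ — positive definiteness is
  guaranteed whenever $\epsilon$ is below the smallest eigenvalue, which
  the function enforces as a precondition.
* **Vine ("average") model**: partial correlations are sampled from a
  Beta$(\alpha, \beta)$ on $[0, 1]$, mapped affinely to $(-1, 1)$, and
  assembled into a full correlation matrix by the recursive C-vine
  construction, which is positive definite by construction. The summary
  this model is calibrated against is the mean absolute off-diagonal
  correlation $\frac{2}{p^2 - p}\sum_{i > j} |\rho_{ij}|$.

### Calibrating the vine mean

`calibrate_mu()` finds the Beta mean $\mu$ (variance $\sigma^2$ fixed,
default 0.1) whose vine draws achieve a target average $|\rho|$, using a
bracketed root search on a common-random-number Monte-Carlo objective.
Numerically the response $\text{avg}|\rho|(\mu)$ at $\sigma^2 = 0.1$ is
U-shaped and symmetric about $\mu = 0.5$, with a floor of about 0.44 at
$p = 20$: the search therefore runs on the increasing branch
$\mu \in [0.5, \mu_{max})$, targets marginally below the floor return the
boundary with a warning, and targets far below it raise an error rather
than pretending to calibrate. Average-correlation targets below the floor
would require a smaller $\sigma^2$; at $\sigma^2 = 0.1$ the moment
inversion itself is only valid for $\mu \in (0.113, 0.887)$, and Beta
shapes near that edge degenerate to two-point distributions whose partial
correlations sit at $\pm 1$. This is a known limitation of the
$(\mu, \sigma^2)$ parameterisation at fixed large variance, and the reason
the calibration is validated by round-trip self-consistency (achieved
average $|\rho|$ within 0.05 of the target) rather than against any fixed
$\mu$ table.

Two numerical guards: sampled partial correlations are clamped to
$|r| \le 1 - 10^{-8}$ (bimodal Beta shapes can draw the numeric
endpoints), and a draw whose smallest eigenvalue falls below $10^{-10}$ in
floating point receives a ridge of order $10^{-9}$ — both orders of
magnitude below any statistically visible digit.

### The kinetic population sampler

`generate_group()` mimics how a cohort of individuals would be measured in
a cross-sectional experiment: each individual gets kinetic parameters
jittered uniformly within ±10% of the base values (rate constants,
Michaelis constants, and the nonzero initial concentrations — zero initial
concentrations stay zero), a condition-wide multiplier $\varepsilon$ scales
all of those parameters (group 1 perturbed, group 2 at
$\varepsilon = 1$), the ODE system is integrated, and concentrations are
read off at a single fixed sampling time.

The packaged model (`oscillator_model()`) is a synthetic five-species
negative-feedback oscillator: a mass-action Brusselator core driving a
linear cascade plus one species with saturable removal. Because its core
terms are all first order in the rate constants, $\varepsilon$ acts to
leading order as a time rescaling — $\varepsilon > 1$ speeds the
oscillation up and $\varepsilon < 1$ slows and flattens it within a fixed
window, with limit-cycle amplitudes stable — which is exactly the
qualitative phenotype the sampler needs and the tests assert
(zero-crossing counts strictly increasing in $\varepsilon$).

The sampling time matters and is configurable. At `t_sample = 20` (the
default) the oscillation phases of jittered individuals have started to
disperse but are not yet uniform: a global $\varepsilon$ shifts how far
that dispersion has progressed, which is what makes the perturbation
visible in the cross-sectional correlation structure. Sampling much later
makes the phases of *both* groups essentially uniform over the same limit
cycle, and the groups become nearly indistinguishable to any association
measure even though the dynamics differ — an instructive failure mode:
detectability of a kinetic perturbation through connectivity depends
strongly on where in the experiment's time course sampling happens, because
small kinetic changes translate into large concentration differences when a
crest or trough is caught. Integration uses the stiff-capable
`deSolve::ode` (lsoda) at `rtol = 1e-8` / `atol = 1e-10`; tolerances are
part of the specification so that runs are bit-reproducible, the step
budget is raised to $10^5$ for strongly accelerated dynamics, divergent
parameter draws raise a simulation error rather than returning garbage,
and tiny negative concentrations from integration error are clipped at
zero.

What the fixture does *not* emulate: the dimensionality (5 species, not
dozens), mass-spectrometry noise and missingness, and any particular
published reaction network. Conclusions from the test suite are about the
method's behaviour on data with oscillator-driven nonlinear dependence, not
about any specific biological system.

## Analytic relationships

For bivariate Gaussians, $MI(\rho) = -\tfrac{1}{2}\ln(1 - \rho^2)$: even,
strictly increasing in $|\rho|$, below the identity for small $|\rho|$ and
above it for large. The crossing $MI(\rho) = \rho$ is found by bisection to
$10^{-6}$; the root is $0.91656\ldots$, conventionally quoted as 0.916
(a truncation — it rounds to 0.917 at three decimals; tests assert
agreement at the quoted value's own precision). This relationship explains
much of the power gap between measures: over most of the correlation range
the MI of linearly related variables is numerically smaller than the
correlation, so MI-based connectivity sums accumulate less signal relative
to their permutation null.

For tie-free data the expected Spearman correlation of a Gaussian pair
with Pearson correlation $\rho$ is
$\rho_S = \frac{6}{\pi(n+1)}\big(\arcsin\rho + (n-2)\arcsin\tfrac{\rho}{2}\big)$,
which maps $0 \mapsto 0$ and $\pm 1 \mapsto \pm 1$ exactly for every $n$
and is biased toward zero in between, the bias shrinking with $n$. The
maximal-bias location is computed numerically: in the large-$n$ limit the
argmax has the closed form $2\sqrt{1 - 9/\pi^2} \approx 0.5937$ and drifts
slightly with $n$. The objective is nearly flat near its maximum — the gap
at the conventionally quoted location 0.577 is within $10^{-3}$ of the
maximal gap — so the package reports the computed argmax rather than
hard-coding either number.

## Experiment drivers and problem sizes

`type1_experiment()`, `power_experiment()` and `kinetic_experiment()`
script the simulation grids: both-groups-null calibration, structured
group 1 versus uncorrelated group 2 (the configuration in which every
feature is differentially connected whenever $\rho > 0$, since the
uncorrelated group's expected connectivity is zero), and kinetic
$\varepsilon$-grids against the $\varepsilon = 1$ reference. A
`contrast = "same_structure"` flag switches the power driver to a
two-draws-from-the-same-model null. Reports are long-format data frames
keyed by cell, with per-replicate detail attached, and are bit-reproducible
from one master seed threaded through every inner call.

Defaults are sized for a desk-scale reproduction: $p = 20$ features,
replicates in the tens, $N_{perm} = 200$ for grids (the single-design
checks use $N_{perm} = 1000$), and the acceptance suite runs the full
type-I design at 100 replicates and the saturated Toeplitz power designs at
$n = 500$ in a few minutes on one core. The Toeplitz grid applies the
Hardin perturbation per replicate except where its eigenvalue precondition
fails (as $\rho \to 1$), in which case the unperturbed matrix is used.

## Known limitations

* MI-based connectivity depends on the binning rule; only histogram
  estimators are implemented (no kernel or nearest-neighbour MI).
* The permutation test destroys *all* association, so it tests the global
  dependence structure per feature, not edge-level differences.
* The hub model's PD repair necessarily distorts the nominal attenuation
  entries at strong $\rho$; exact-structure checks apply to the raw matrix
  or to PD-safe parameter ranges.
* The vine calibration cannot reach average correlations below the
  $\sigma^2$-dependent floor described above.
* Negative and positive associations are indistinguishable in the
  connectivity sum (absolute values), and MI is sign-blind by
  construction.
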