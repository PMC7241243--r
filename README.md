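# diffconn

Differential connectivity analysis for feature–feature association networks.

## The problem

In metabolomics (and other omics fields) a condition is often characterised
not by shifts in individual feature levels but by changes in how features
co-vary. Given measurements of *p* features in two groups — cases and
controls, male and female, perturbed and unperturbed — each group defines a
weighted association network: nodes are features, and the edge weight
between features *i* and *j* is an association measure *a<sub>ij</sub>*,
either a correlation (Pearson or Spearman) or the mutual information (MI)
between their levels. The **connectivity** of feature *i* in a group is

> χ<sub>i</sub> = Σ<sub>j≠i</sub> |a<sub>ij</sub>|,

the weighted generalisation of node degree, and the **differential
connectivity** between groups 1 and 2 is

> Δχ<sub>i</sub> = χ<sub>i</sub><sup>G1</sup> − χ<sub>i</sub><sup>G2</sup>.

Significance is assessed with a column-permutation test: each column of both
data matrices is independently shuffled (destroying all associations while
preserving every marginal), the permuted Δχ is recomputed N<sub>perm</sub>
times to form a per-feature null distribution D<sub>i</sub>, and

> P<sub>i</sub> = (1 + #{|D<sub>i</sub>| > |Δχ<sub>i</sub>|}) / N<sub>perm</sub>,

clipped to 1. Features with P<sub>i</sub> < α are declared differentially
connected.

The package implements this test for all five association measures
(Pearson, Spearman, and MI under empirical, Miller–Madow, James–Stein
shrinkage, and Schurmann–Grassberger entropy estimation), together with the
simulation machinery needed to study its operating characteristics:

* structured random correlation matrices — Toeplitz/AR(1)
  (Σ<sub>ij</sub> = ρ<sup>|i−j|</sup>), hub groups with attenuating
  hub–member correlation, and vine-sampled matrices calibrated to a target
  average |ρ| — with Hardin-style random perturbation and multivariate
  Gaussian sampling;
* a kinetic ODE population sampler: per-individual ±10% uniform jitter of
  all rate constants, Michaelis constants, and nonzero initial
  concentrations, plus a global perturbation multiplier ε applied to all of
  them, with a built-in five-species oscillator model (synthetic);
* the closed-form relationships MI(ρ) = −½ ln(1 − ρ²) for bivariate
  Gaussians (which crosses the identity at ρ ≈ 0.916) and the expected
  Spearman–Pearson mapping ρ<sub>S</sub>(ρ, n);
* scripted experiment grids for type-I error, power versus
  (structure, ρ, n, measure), and kinetic power versus (ε, n, measure),
  with two-measure overlap summaries.

## A worked example

Group 1 follows a Toeplitz (ρ = 0.7) correlation structure, group 2 is
uncorrelated noise, so every feature is genuinely differentially connected:

```r
library(diffconn)

x1 <- sample_gaussian(toeplitz_matrix(8, 0.7), n = 150, seed = 11)
x2 <- matrix(rnorm(150 * 8), 150, 8); colnames(x2) <- colnames(x1)

fit <- dc_test(x1, x2, measure = "pearson", n_perm = 1000, seed = 42)
summary(fit)
#> Differential connectivity test (pearson)
#>   groups: n1 = 150, n2 = 150, features = 8
#>   permutations: 1000, alpha = 0.05
#>   significant features: 8 / 8
#>
#> Features ordered by significance:
#>  feature   chi_g1    chi_g2 delta_chi p_value significant
#>       V3 3.100177 0.4647152  2.635462   0.001        TRUE
#>       V5 3.099937 0.4935788  2.606358   0.001        TRUE
#>       V4 2.853509 0.4562605  2.397249   0.001        TRUE
#>       V2 2.761829 0.3737816  2.388047   0.001        TRUE
#>       V6 3.006436 0.6237946  2.382641   0.001        TRUE
#>       V7 2.478940 0.4336407  2.045299   0.001        TRUE
#>       V8 2.110537 0.5209587  1.589578   0.001        TRUE
#>       V1 1.975701 0.4912156  1.484485   0.001        TRUE
```

Interior features (V3–V6) have two strongly correlated neighbours on each
side, so their group-1 connectivity — and hence Δχ — exceeds that of the
chain ends (V1, V8). The group-2 connectivities around 0.4–0.6 are pure
finite-sample noise (the population value is 0). Every feature attains the
smallest possible p-value 1/N<sub>perm</sub> = 0.001.

`coef(fit)` returns the Δχ vector, `plot(fit)` draws it with significant
features highlighted, and `write_dc_result(fit, path)` stores the table as
CSV. The same analysis runs from the shell via the installed
`cli/diffconn` script (subcommands `run`, `simulate`, `experiment`,
`analytic`).

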