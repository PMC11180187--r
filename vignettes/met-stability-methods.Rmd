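---
title: "Models and methods behind metstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

A multi-environment trial (MET) grows the same set of genotypes at several
locations or under several managements. When genotype rankings change across
environments — genotype-by-environment interaction (GEI) — neither a single
"best" genotype nor a single average tells the breeder much. `metstab`
implements the standard toolkit for quantifying and exploiting GEI: the AMMI
model, GGE biplot geometry, a suite of univariate stability statistics, and
the MGIDI multi-trait selection index. The package ships the grain-yield
means of a published two-regime irrigation trial (five rice genotypes, nine
environments, three replicates, analysed separately under alternate
wetting-and-drying and continuous flooding) as its worked fixture, and a
split-plot simulator with planted structure as its test bed.

## The AMMI model

For a complete genotype × environment table of cell means $x_{ij}$, AMMI
fits additive main effects by ANOVA and models the residual interaction by a
singular value decomposition of the doubly-centred matrix

$$z_{ij} = x_{ij} - \bar x_{i.} - \bar x_{.j} + \bar x_{..}
        = \sum_{k} \lambda_k \alpha_{ik} \gamma_{jk}.$$

Axis $k$ explains $\lambda_k^2 / \sum_m \lambda_m^2$ of the GEI sum of
squares. Choices made here:

* **Partitioning.** Genotype and environment scores both carry
  $\sqrt{\lambda_k}$ (symmetric partition), so the score product
  reconstructs $z_{ij}$ exactly. This is the common biplot default and makes
  the AMMI1 nominal-yield line $\hat y_i(t)=\bar x_{i.}+s_{i1}t$ agree with
  the rank-1 model prediction.
* **Sign convention.** An SVD axis is defined up to sign; each axis is
  oriented so its largest-magnitude *environment* score is positive, making
  outputs reproducible across platforms.
* **Degrees of freedom and tests.** With replicate data the ANOVA adds
  REP(ENV) ($e(r-1)$ df) and a pooled error ($e(g-1)(r-1)$ df); each axis is
  tested against the pooled error with Gollob df $g+e-1-2k$. With means
  only, F and p are reported as `NA` rather than approximated — mean squares
  need a replicate-level error.
* **The Gollob test is liberal.** Because the first axis maximizes the
  interaction SS, its F-test rejects a true null well above the nominal
  rate (about 0.2 at nominal 0.05 in the package's own null simulations at
  the 5 × 9 × 3 design). The test suite asserts this honestly — inflated
  but bounded, with power above the null rate — rather than pretending the
  test is exact. Treat the axis p-values as a screening heuristic.
* **Degenerate inputs.** A purely additive matrix has all
  $\lambda_k \approx 0$; axis shares are then reported as `NA` (the share of
  nothing is not 0% or 100%). The threshold is a standard
  dimension-scaled machine-epsilon cutoff on $\lambda_1$.

The AMMI stability value weights a genotype's first-axis score by the ratio
of axis-1 to axis-2 interaction sums of squares,
$ASV_i = \sqrt{((SS_1/SS_2)\,s_{i1})^2 + s_{i2}^2}$, ranked ascending.

## GGE biplots

The GGE model removes only environment means ($x_{ij}-\bar x_{.j}$), keeping
genotype main effect plus interaction ("G+GE") in the decomposition, with no
column scaling. Axis shares are computed against the total G+GE SS over all
axes, matching how PC1 percentages are conventionally reported. The
singular-value partition is selectable; the defaults follow standard GGE
practice — symmetric for which-won-where, genotype-focused when comparing
genotypes, environment-focused when comparing environments. The geometry is
entirely 2-D (hull on the first two axes), as the biplots it supports are.

Which-won-where assigns each environment to the hull vertex maximizing the
score inner product, which equals the argmax of the 2-axis fitted value;
ties break by label order. The average-environment-coordinate (AEC) axis is
the unit vector toward the mean environment score: projections onto it order
genotypes by fitted mean performance, perpendicular distance measures
instability; the ideal genotype sits on the AEC at the largest observed
projection, the ideal environment along the AEC at the longest environment
vector. The AEC axis is undefined (an error) when the mean environment
score is numerically zero.

## Stability statistics

All statistics operate on a complete means matrix; ranking direction is
rank 1 = highest yield within an environment, with average ranks on ties
(the same convention the Spearman correlations use).

* **Ecovalence** $W_i^2=\sum_j z_{ij}^2$ partitions the GEI SS exactly.
* **Joint regression** regresses each genotype on the environment index
  $\bar x_{.j}-\bar x_{..}$; the deviation mean square uses $e-2$ df.
  Slopes average to 1 on balanced data.
* **Huehn S1, S2** use raw within-environment ranks; **S3, S6** rank the
  corrected values $x_{ij}-\bar x_{i.}+\bar x_{..}$, per the original
  definitions, so they measure rank instability net of genotype level.
* **Thennarasu NP1–NP4** rank the adjusted values
  $x_{ij}-(\bar x_{i.}-\bar x_{..})$; denominators use the raw-rank medians
  and means.
* **Lin–Binns superiority** splits environments into favorable
  (environment mean ≥ grand mean; ties favorable — a deterministic split)
  and unfavorable subsets.
* **RPGV/HMRPGV** estimate variance components by the balanced
  method-of-moments (closed-form, fully testable; REML adds nothing on a
  balanced design), truncating negative estimates to zero with a warning,
  and shrink genotype and interaction effects by
  $c_g = re\sigma^2_g/(re\sigma^2_g+r\sigma^2_{ge}+\sigma^2_\varepsilon)$
  and $c_{ge} = r\sigma^2_{ge}/(r\sigma^2_{ge}+\sigma^2_\varepsilon)$.
  The genotypic value is referenced to each environment mean,
  $RPGV_{ij}=GV_{ij}/\mu_j$; HMRPGV is the plain harmonic mean
  $e/\sum_j RPGV_{ij}^{-1}$. (A commonly printed variant of that formula
  carries an extra inner $n$ that would cancel the environment count
  altogether; the harmonic mean is what the statistic's name and use
  require.) Note that with unequal environment means, the mean of
  $GV_{ij}/\mu_j$ is not exactly $\bar x_{i.}/\bar x_{..}$ even without
  shrinkage — a Jensen-type gap of order the squared variation in
  $1/\mu_j$ — which the tests acknowledge.

## MGIDI

Traits are first mapped linearly to $[0,100]$ with 100 at the desirable
extreme (declared per trait as increase/decrease). Factor analysis then
eigen-decomposes the trait correlation matrix, retains factors with
eigenvalue ≥ 1 (Kaiser), varimax-rotates with Kaiser normalization, and
scores genotypes by the regression method. Two numerical choices matter:

* The correlation matrix is inverted by Moore–Penrose pseudoinverse, so the
  index works with fewer genotypes than traits (a 5-genotype, 6-trait panel
  has a rank-deficient correlation matrix by construction).
* Rotation signs are fixed by making each factor's largest-|loading|
  positive. Loadings are therefore comparable only up to sign with other
  software.

The ideotype is the all-100 row pushed through the same standardization and
scoring map; MGIDI is the Euclidean distance between a genotype's factor
scores and the ideotype's, ranked ascending, selecting
$\max(1,\mathrm{round}(p\,g))$ genotypes at pressure $p$ (one of five at the
default $p=0.2$). Selection gains take SD = Xs − Xo and SG = SD·h², with
heritabilities accepted on either the unit or percent scale; gains can also
be computed from a directly supplied SD, which is how the published
gain-table arithmetic is reproduced (printed Xs − Xo values lose a digit to
rounding). Factor contributions $(s_{if}-s^{ideo}_f)^2/MGIDI_i^2$ give the
strengths-and-weaknesses decomposition; a genotype exactly at the ideotype
gets uniform contributions and a degeneracy flag.

## The simulator

`simulate_met()` draws from the model AMMI assumes:
$y_{ijr}=\mu+g_i+e_j+\sum_k\lambda_k\alpha_{ik}\gamma_{jk}+\varepsilon_{ijr}$,
with $\alpha,\gamma$ orthonormal, zero-sum score vectors built by
QR-orthonormalization of column-centred Gaussian draws — exactly the
identifiability constraints of the decomposition, so a noise-free fit
recovers the planted $\lambda$ to machine precision. Defaults mirror the
fixture trial: $g=5$, $e=9$, $r=3$, $\mu=4.85$ t/ha, genotype/environment
effect SDs 0.13/0.30 t/ha (the spread of the fixture margins),
$\lambda=(1.0,0.6)$ (sized to the fixture's GEI SS), and plot error 0.42
t/ha, which puts the cell-mean coefficient of variation near 5%, a typical
precision for yield trials of this kind. A single integer seed drives one
RNG stream.

The whole-plot (irrigation-regime) stratum of the split-plot design is not
simulated separately: all downstream statistics operate per regime on entry
means, so a single residual suffices for what the package tests.
`simulate_multitrait()` plants correlated genotype effects across traits
(any positive semi-definite correlation, so perfectly correlated traits are
allowed) and realizes each trait's entry-mean heritability by sizing the
plot error as $re\,\sigma^2_g(1-h^2)/h^2$.

What the simulator does *not* emulate: spatial field trend, unbalanced or
missing cells, multi-year structure, non-normal error, and
genotype-specific error variances. Passing tests on simulated data
therefore validate the algebra and the estimators under the stated model,
not robustness to those features of real data.

## Validation scale and known limits

The property suite runs hundreds of small trials (5 × 9 × 3; 200
replicates for the recovery and null-calibration checks; 50 random matrices
against the brute-force rank-statistic oracles), which keeps the full test
run under a minute. Two estimator facts surfaced by those checks are worth
restating: the AMMI PC1-share estimator is biased downward when plot noise
is comparable to the interaction (at the fixture-scale GEI with plot error
0.2 t/ha, the mean absolute deviation from the planted share is ~9 points;
at a strong planted interaction, ~2.5), and the Gollob axis test is
liberal under the null. Neither is a defect of the implementation; both are
properties of the method that users should know.

The embedded fixtures are printed to 2 decimal places, which caps how
precisely any derived quantity can be reproduced: axis shares are checked
to ±1.5 percentage points and marginal means to half a unit of the last
digit. A handful of close geometric calls (which genotype has the smallest
first-axis score, which environments have the longest second-axis spokes,
the ideal-genotype order under continuous flooding) are sensitive at
exactly that rounding level; for these the package asserts what the SVD of
the printed matrices actually yields, and `reproduce_paper()` reports the
qualitative comparisons without gating on them.
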