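# metstab

Stability analysis for multi-environment trials (METs): AMMI, GGE biplot
geometry, univariate stability statistics, and the MGIDI multi-trait
selection index, with a split-plot simulator for validation.

## What it does

When the same genotypes are grown in several environments, rankings often
change from site to site — genotype-by-environment interaction (GEI). The
package quantifies that interaction and turns it into selection decisions:

* **AMMI** — two-way ANOVA for main effects plus SVD of the doubly-centred
  interaction matrix `z_ij = x_ij − x̄_i. − x̄_.j + x̄_..`; per-axis shares
  of the GEI sum of squares, Gollob F-tests from replicate data, AMMI1/AMMI2
  biplot coordinates, the nominal (adaptation) plot, and the AMMI stability
  value `ASV = sqrt(((SS1/SS2)·s1)² + s2²)`.
* **GGE** — SVD of the environment-centred matrix (genotype main effect +
  GEI) under selectable singular-value partitioning; which-won-where hull
  and sectors, mean-vs-stability along the average environment coordinate,
  ideal-genotype and ideal-environment rankings.
* **Stability statistics** — Wricke's ecovalence, joint regression (b,
  S²d), Huehn's S1/S2/S3/S6, Thennarasu's NP1–NP4, Lin–Binns superiority
  (all/favorable/unfavorable), geometric adaptability index, BLUP-based
  RPGV and HMRPGV, and Spearman correlations among all measures.
* **MGIDI** — 0–100 trait rescaling toward a declared ideotype, factor
  analysis (Kaiser retention, varimax), Euclidean genotype–ideotype
  distance on factor scores, selection at a given pressure, per-trait
  selection differentials/gains, and a strengths–weaknesses decomposition.
* **Simulator** — balanced split-plot METs with planted additive effects,
  low-rank interaction with orthonormal score vectors, per-trait
  heritabilities and trait correlations; every downstream stage is tested
  against planted truth.

The package embeds, as fixtures, the grain-yield means of a published
two-regime irrigation trial of five rice genotypes in nine environments
(three replicates; alternate wetting-and-drying vs continuous flooding),
available via `yield_fixture("AWD")` / `yield_fixture("CF")`.

## Worked example

```r
library(metstab)

m <- yield_fixture("AWD")
fit <- ammi_fit(m)
round(fit$pct_gei, 1)
#> [1] 59.1 25.7  9.2  6.0
round(fit$cum_pct[2], 1)
#> [1] 84.8

gge <- gge_fit(m, "genotype")
ideal_genotype_ranking(gge)$genotype
#> [1] "G3" "G4" "G1" "G5" "G2"

st <- stability_table(m)
st$values$genotype[which.min(st$values$ASV)]
#> [1] "G1"
```

The first two AMMI axes carry 84.8% of the AWD interaction sum of squares,
so a 2-D biplot summarizes the GEI faithfully; G3 is the closest genotype
to the GGE ideal point (high mean, low instability) and G2 the farthest;
G1 has the lowest AMMI stability value (most stable by that measure).

The numbered scripts under `analysis/` walk the full sequence — fixture
margins, AMMI, GGE geometry, the stability suite, MGIDI on a simulated
six-trait panel, and simulation diagnostics — writing their tables under
`results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

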