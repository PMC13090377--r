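# singulOR

Quantifying singular olfactory receptor (OR) expression in developing
olfactory sensory neurons, from single-nucleus and imaging-based spatial
transcriptomics.

Mature olfactory sensory neurons obey the one-neuron/one-receptor rule:
each neuron expresses a single OR gene out of a family of hundreds. Testing
whether that singularity is already present in fetal immature neurons
(iOSN) and their precursors (INP) requires statistics that behave well on
extremely sparse OR counts. `singulOR` provides them for R users working
with `SingleCellExperiment` objects:

* **Per-cell OR dominance score.** For top and second OR counts
  x₁ ≥ x₂,

  D = ((x₁ − x₂) / (x₁ + x₂ + ε)) · log(1 + x₁),  ε = 1e−9,

  zero for OR-negative cells; high-dominance cells are D > 1, top OR ≥ 1,
  ≤ 3 co-expressed ORs (`dominanceScore`, `orCellSummary`,
  `classifyHighDominance`, `binDominance`, `dominantORFrequency`,
  `diagonalOrder`).
* **Contingency statistics.** Cell identity × OR-count category (0/1/2/3+)
  tables, Pearson χ² (no continuity correction), Cramér's
  V = √(χ²/(N·min(r−1, c−1))) with a seeded multinomial-bootstrap CI, and
  bin-vs-rest post-hoc χ² tests with Benjamini–Hochberg correction
  (`orContingencyTest`, `cramersV`, `posthocPerBin`).
* **Maternal-contamination QC.** Sex score
  S = log₂((XIST + 1)/(ΣY + 1)) on log-normalized values, erythroid score
  over the hemoglobin panel, strict-majority sample-sex voting, and
  contamination flags for discordant + erythroid-high cells (`runSexQC`,
  `basicCellFilters`).
* **Pseudobulk composition.** Donor-level proportions
  P(d,c) = N(d,c)/Σ N(d,·), Kruskal–Wallis stage tests with a
  three-donor presence rule, Wilcoxon sex tests
  (`pseudobulkProportions`, `stagewiseTest`, `sexFractionTest`).
* **Spatial axis binning.** 12-transcript filtering, projection of
  segmented cells onto a user-drawn axis polyline, 50 equal-width bins,
  row-scaled cell-type profiles, per-bin gene means, OR density maps
  (`filterLowCountCells`, `spatialBinProfile`, `orDensityMap`,
  `spatialHighDominanceSummary`).
* **Synthetic cohorts with ground truth.** A seeded generator for
  multi-donor, multi-stage cohorts with monogenic OR choice, minority
  co-expression, OR background, planted maternal contamination, and a
  respiratory→olfactory spatial strip (`simulateCohort`,
  `plantContamination`, `simulateSpatialStrip`,
  `expectedSingleORFraction`).

Counts travel as Matrix Market triplets with tab-delimited gene/cell
sidecars (`readCohort` / `writeCohort`), held in memory as a
`SingleCellExperiment`.

## Worked example

```r
library(singulOR)
tab <- exampleORCategoryCounts()       # bundled worked-example counts
tab
#>      0   1  2 3+
#> INP  233  87 21  9
#> iOSN 166 208 47 15
orContingencyTest(observed = tab, bootstrapCI = TRUE, B = 10000, seed = 1)
#> ContingencyResult: 2 x 4 table, N = 786
#>   chi2 = 63.6749 (df = 3), p = 9.63e-14
#>   Cramer's V = 0.285 (95% CI 0.222-0.355)
#>   per-bin post-hoc (BH-adjusted):
#>     0      padj = 7.92e-15   ***
#>     1      padj = 9.72e-11   ***
#>     2      padj = 0.0238     *
#>     3+     padj = 0.482      ns
```

The bundled table is the distribution of OR-count categories among 350 INP
and 436 iOSN in a developing human olfactory epithelium. The χ² test shows
a strong association between cell identity and OR-count category (V =
0.285): OR-negative cells are over-represented among precursors, cells with
one or two receptors among immature neurons, while ≥3-receptor
co-expression is equally rare in both — the pattern expected if receptor
choice is resolving toward singularity as neurons mature.

A full synthetic round trip:

```r
cfg <- simulationConfig(seed = 1, monogenicFraction = 0.8)
sce <- simulateCohort(cfg)
sm  <- orCellSummary(sce)
pos <- sm$cell_type == "iOSN" & sm$n_expressed >= 1
c(observed = mean(sm$n_expressed[pos] == 1),
  expected = expectedSingleORFraction(0.8))
#>  observed  expected
#> 0.8419958 0.8577932
```

See `vignettes/singulOR-methods.Rmd` for the models, parameter choices and
their rationale.

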