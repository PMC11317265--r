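# tlsQuant

Quantification and prognostic analysis of tertiary lymphoid structures
(TLSs) in solid tumours, with defaults tuned for gastric adenocarcinoma.

TLSs are organized lymphoid aggregates that form in tumour tissue. Their
prognostic impact depends on three things this package quantifies jointly:

* **abundance** — counts and densities (per mm²) of TLS events;
* **maturation** — E-TLS (early aggregate) / PFL-TLS (follicular dendritic
  cells, no germinal centre) / SFL-TLS (germinal centre present);
* **location** — tumour centre (CT) versus invasive margin (IM), the
  2.5 mm band on each side of the tumour boundary.

For pathologists and biostatisticians analysing annotated tumour sections,
the package computes the six spatial TLS scores (CT/IM/Total × count and
density, plus germinal-centre-restricted variants) and carries them through
survival analysis: maximally selected rank-statistic cutpoints
(`maxstatCutpoint`), Kaplan–Meier and log-rank (`kmEstimate`,
`logrankTest`), univariate/multivariate Cox with Efron tie handling
(`coxFit`), and association tables against clinicopathological variables
(`associationTable`). For transcriptome cohorts it scores TLS /
germinal-centre / dendritic-cell gene signatures per sample with ssGSEA
(`ssgseaScore`), dichotomizes them against survival (`dichotomize`), and
runs two-class GSEA between the groups (`gseaTwoClass`). For multiplex
immunofluorescence it phenotypes cell tables by marker thresholds, computes
per-compartment composition percentages and co-expression fractions, and
clusters co-infiltration profiles (`phenotypeCells`, `compositionSummary`,
`coinfiltrationCluster`). Synthetic generators
(`simulateExpressionCohort`, `simulateTissueCohort`,
`simulateCellTables`) produce inputs for all three arms with the planted
statistical structure the methods are meant to detect.

The core spatial statistic: for a tumour boundary polygon, the IM is the
symmetric buffer of half-width *w* = 2.5 mm around the boundary curve, the
CT is the interior beyond the buffer, and each density is

    D_zone = N_zone / A_zone   [TLS per mm²],
    Total-TLS-D = (N_CT + N_IM) / (A_CT + A_IM),

with zone membership decided by exact point-to-boundary distance (ties at
*w* go to the IM) and areas by dense grid quadrature (within 0.5% of
analytic values on reference geometries).

## Worked example

Simulate a 166-case histology cohort with a planted protective effect of
germinal-centre-positive IM TLSs, score it, find the optimal density
cutpoint, and fit the survival contrast:

```r
library(tlsQuant)

tissue <- simulateTissueCohort(tissueSimConfig(nCases = 166, seed = 1))
tissue$partition
#> ZonePartition: 256 boundary vertices, band 2.5 mm
#>   area CT: 171.303 mm^2  area IM: 330.565 mm^2
#>   note: no tissue extent given; IM extends the full band outward

sc <- computeTLSScores(tissue$events, tissue$partition)
head(scoreTable(sc)[, c("case_id", "IM_TLS_N", "IM_TLS_D", "IM_TLS_D_GC")], 3)
#>    case_id IM_TLS_N  IM_TLS_D IM_TLS_D_GC
#> 1 case_001       86 0.2601609  0.07865329
#> 2 case_002       76 0.2299096  0.08470354
#> 3 case_003       66 0.1996584  0.06655279

surv <- tissue$survival
x <- scoreTable(sc)$IM_TLS_D_GC[match(surv$id, scoreTable(sc)$case_id)]
ms <- maxstatCutpoint(x, surv$time_months, surv$event, nPerm = 999, seed = 1)
ms
#> Maximally selected log-rank statistic
#>   cutpoint: 0.0922664  M: 3.3638  p (permutation): 0.012
#>   13 candidate cutpoints, minprop 0.10

grp <- factor(ifelse(x > ms$cutpoint, "high", "low"), c("low", "high"))
logrankTest(surv$time_months, surv$event, grp)$p.value
#> [1] 0.0007704881

coxFit(data.frame(surv, group = grp), "group")[, c("term", "HR", "ci_low",
                                                   "ci_high", "p")]
#>        term        HR    ci_low   ci_high           p
#> 1 grouphigh 0.4750861 0.3049468 0.7401514 0.001001088
```

Cases with a high density of GC-positive IM TLSs have less than half the
hazard of the low-density group (HR 0.48, 95% CI 0.30–0.74) — the
generator's planted protective effect, recovered end to end through zone
partitioning, maturation-restricted density scoring, cutpoint selection
and Cox regression. `runPipeline()` wires the same stages (plus the
transcriptome and mIF arms) into one call, and `renderReports()` writes
the tables as TSVs.

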