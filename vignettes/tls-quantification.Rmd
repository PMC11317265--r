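---
title: "Quantifying tertiary lymphoid structures: models, scores and design choices"
author: "tlsQuant"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsQuant)
```

# The problem

Tertiary lymphoid structures (TLSs) are organized lymphoid aggregates that
assemble in chronically inflamed, non-lymphoid tissue — including solid
tumours — and recapitulate much of the architecture of a lymph node. Three
properties of tumour-associated TLSs carry prognostic information in
gastric adenocarcinoma and related cancers:

* **abundance** — how many TLSs a section contains, absolutely and per unit
  area;
* **maturation** — early aggregates (E-TLS), primary follicle-like
  structures containing follicular dendritic cells but no germinal centre
  (PFL-TLS), and secondary follicle-like structures with a germinal centre
  (SFL-TLS). GC presence dominates the staging: any GC-positive aggregate
  is SFL regardless of its FDC status;
* **location** — the tumour centre (CT) versus the invasive margin (IM),
  the band extending 2.5 mm on each side of the tumour boundary.

`tlsQuant` implements the full analysis chain around these quantities in
three arms: a transcriptome arm (gene-signature scoring of bulk expression
cohorts), a histology arm (spatial scoring of annotated sections plus
survival modelling), and a multiplex-immunofluorescence (mIF) arm
(cell-level composition of TLSs). A synthetic-data module generates inputs
for all three arms with the statistical structure the analysis assumes, so
the pipeline is fully testable without patient data.

# Transcriptome arm

## ssGSEA scoring

Per-sample signature scores use single-sample gene-set enrichment: within
each sample, genes are ranked by expression in decreasing order and given
the rank statistic $N..1$. Walking down the ranking, the running sum gains
$|r_i|^{\alpha} / \sum_{j \in S} |r_j|^{\alpha}$ at in-set genes and loses
$1/(N - |S|)$ at out-of-set genes; the score is the sum of the running-sum
values over all $N$ positions. The default $\alpha = 0.25$ is the canonical
parameterization of this statistic. Because the score depends on the
expression values only through their per-sample ordering, it is invariant
under any strictly increasing per-sample transform — which is also why the
synthetic cohort generator only needs to plant *monotone* latent structure
(see below). Ties in the ranking are broken by gene symbol,
lexicographically, so scores are bit-reproducible.

Built-in signatures: the 12-chemokine TLS signature (CCL2/3/4/5/8/18/19/21,
CXCL9/10/11/13) and the germinal-centre signature (CD21, CD23, CXCL13,
given as surface-marker names and normalized through a small alias table to
CR2, FCER2, CXCL13). The activated-dendritic-cell slot ships a
**placeholder** list (LAMP3, CD83, CCR7, CD80, CD86, CD40): the published
DC and immune-cell lists this analysis style relies on are not
redistributed here, and users should supply their own via `readGMT()`.

## Dichotomization

Samples are split into signature-high (`+`) and signature-low (`-`) groups
by a cutoff. The default cutoff machinery is maximally selected rank
statistics against overall survival (below), because that is the stated
cutpoint method of the histology analyses this package mirrors; the median
and fixed cutoffs are offered for cohorts where no survival-driven
threshold is wanted. The cutoff and method are recorded on the score table.

## Two-class GSEA

Pathway enrichment between the `+` and `-` groups ranks genes by the
signal-to-noise statistic $(\mu_+ - \mu_-) / (\sigma_+ + \sigma_-)$, with
each class standard deviation floored at $\max(0.2\,|\mu|, 10^{-8})$, and
computes the weighted Kolmogorov–Smirnov enrichment score (weight exponent
1). Nominal p-values come from phenotype permutations that preserve class
sizes; the normalized enrichment score divides the observed ES by the mean
same-sign permuted |ES|, and the FDR q-value is the standard NES-based
ratio estimate. Permutations are seeded, so results are reproducible.

# Histology arm

## Zone partition

The tumour boundary is a simple closed polygon in millimetres. The IM is
the set of points within `bandWidth` (default 2.5 mm) of the boundary curve
on either side — a symmetric buffer of total width 5 mm — and the CT is the
remaining interior. Points at exactly the band distance belong to the IM;
this tie rule also fixes the outer IM frontier. When a tissue-extent
polygon is provided, the outward reach of the IM is clipped to it;
otherwise tissue is assumed present for the full band and the assumption is
flagged in the partition metadata.

Zone *membership* is exact (point-in-polygon plus point-to-polyline
distance, both in compiled code). Zone *areas* are computed by mid-point
quadrature on a regular grid over the padded bounding box; at the default
resolution (`gridN = 720`) the areas of a 512-vertex circle of radius 10 mm
with a 2.5 mm band are within 0.03% of the analytic annulus values, an
order of magnitude tighter than the 0.5% the package treats as acceptable.
Curved boundaries should be sampled at 128 vertices or more (a warning
reminds the user). An inward offset that empties the CT (a tumour thinner
than twice the band) is legitimate and reported, not an error.

Events straddling no zone (beyond the IM's outer frontier) are excluded
from scoring with a logged count; TLSs are assigned whole, by their
centroid coordinates.

## The six TLS scores

Per case: CT-TLS-N, IM-TLS-N and Total-TLS-N are event counts in the CT,
the IM and their union; each density (CT-TLS-D, IM-TLS-D, Total-TLS-D)
divides the corresponding count by the corresponding area in mm², with the
Total density dividing the summed count by the summed area (not averaging
the zone densities). GC-restricted variants repeat all six over SFL events
only. A density over a zero-area zone is reported as missing, never as 0.

## Survival statistics

Kaplan–Meier estimation, the log-rank test and Cox proportional-hazards
regression delegate to the `survival` package, with the conventions fixed
as: deaths precede censorings at tied times; Efron tie handling in Cox
models (Breslow available); 95% Wald confidence intervals
$\exp(\beta \pm 1.96\,\mathrm{se})$. A monotone partial likelihood
(perfect separation) is surfaced as a warning and a flag rather than an
error.

Maximally selected rank statistics are implemented in the package (no
installed package provides them): candidate cutpoints are the midpoints
between consecutive distinct marker values whose split keeps at least
`minprop` (default 0.1) of subjects on each side; each candidate's
standardized two-group log-rank statistic is computed in compiled code, and
the cutpoint maximizes the absolute statistic (exact ties resolve to the
smallest candidate). The default p-value is by permutation of the marker
across subjects — exact in distribution at any scale, seeded, with the
$(1 + k)/(B + 1)$ estimator — because at cohort sizes of a few hundred the
permutation null is affordable and avoids approximation error; the
Lausen–Schumacher normal approximation is available as an option.

# Association statistics

Contingency tests default to the *uncorrected* Pearson chi-square: this is
the variant that reproduces the published association p-values this
package's acceptance checks pin down (0.1746, 0.3181, 0.7812, 0.0469,
0.0458 on the printed 2×2 tables), with Yates correction as an option. The
two-sided Fisher exact test (probability-ordering rule) substitutes
automatically in `associationTable()` for 2×2 tables with any expected
count below 5, the regime where the chi-square approximation is
unreliable and where published sparse rows (p = 0.999) indicate an exact
test was used. Note the two tests agree closely only where they
discriminate: for mid-range p their two-sided p-values can differ by more
than 0.05 even with large expected counts, which is why the package's
internal consistency check conditions on p < 0.1. Location comparisons use
the classical equal-variance two-tailed t test, one-way ANOVA, or the
Wilcoxon rank-sum test (exact enumeration when both groups have at most 10
untied observations). Significance stars follow *p<0.05, **p<0.01,
***p<0.001, ****p<0.0001.

# mIF arm

Cells arrive as a table of per-cell marker intensities (CD20, CD8, FOXP3,
CD23, DC-LAMP, PD-1) with compartment labels (CT/IM × TLS-with-GC,
TLS-without-GC, stroma). Phenotypes are conjunctions of per-marker
positivity at fixed thresholds (or thresholds computed per marker by Otsu's
method, provided because acquisition software thresholds are rarely
published). Percentages use the HALO-style denominator — all cells in the
compartment — and pooling across compartments is count-weighted, never an
average of percentages. PD-1-positive fractions are likewise reported
among all compartment cells, a choice the package documents because the
alternative (among lymphocytes only) is equally defensible.
Co-infiltration clustering of the four co-expression phenotypes
(PD1+CD20+, FOXP3+CD8+, PD1+CD8+, PD1+FOXP3+) uses agglomerative
clustering with Euclidean distance and average linkage on the raw percent
scale (an optional z-score switch is recorded in the output); these
defaults are chosen for determinism, since no linkage is standard in this
literature.

# The synthetic-data module

The generators define the study conditions under which the package's
properties are demonstrated; they are first-class, tested code.

**Expression cohorts** (`simulateExpressionCohort`): each sample carries a
latent TLS abundance $L \sim N(0,1)$; signature genes gain $w\,L$ on top of
a gene-specific baseline plus $N(0, \sigma)$ noise, non-signature genes
only baseline plus noise. Because ssGSEA is rank-based, this additive
monotone structure is sufficient — no attempt is made to mimic microarray
distributions. Survival is exponential with hazard
$h_0 \exp(\beta_L L)$, administratively censored. Defaults: $n = 300$
samples (a GEO-scale cohort), 2000 genes, $w = 1$, $\sigma = 1$,
$\beta_L = -0.5$ (high TLS abundance protective), $h_0 = 0.02$/month,
censoring at 60 months. The latent truth is retained only in object
metadata and a sidecar JSON, never in analysis-facing exports.

**Tissue cases** (`simulateTissueCohort`): the boundary is a star-shaped
curve $R(\theta) = R_0 (1 + \sum_k a_k \cos(k\theta + \phi_k))$ — simple by
construction as long as the radius stays positive (violations are rejected
naming the offending harmonic) — shared by all cases of a configuration so
the zone partition is built once. TLS events are homogeneous Poisson in
each zone ($\lambda_{CT} = 0.08$, $\lambda_{IM} = 0.25$ per mm² by
default), with maturation drawn from zone-specific multinomials (CT:
0.5/0.3/0.2, IM: 0.35/0.3/0.35 over E/PFL/SFL; no published per-zone
mixture exists, so these are free parameters chosen to make SFL events
common enough at the margin to score). Survival has hazard
$h_0 \exp(\beta\, d)$ with $d$ the case's IM-SFL density. The default
$\beta = -33$ per (TLS/mm²) was derived analytically from the default
geometry: the density's Poisson variation gives $\sigma_d \approx 0.017$,
a median split separates group means by $\approx 1.6\,\sigma_d$, and
$\exp(-33 \times 0.028) \approx 0.4$ — the protective hazard ratio scale
reported for GC-positive IM TLSs. The baseline $h_0 = 0.27$/month is the
hazard at *zero* density, calibrated so the hazard at the typical density
($\approx 0.0875$/mm²) is $\approx 0.015$/month, a realistic cohort event
rate.

For parameter-recovery checks that plant an *exact* hazard ratio on the
dichotomized high/low density group, `simulateSurvivalCohort` draws the
binary group directly (default split 0.735 high, matching the observed
high/low proportions of the motivating cohort) with exponential times at
hazard ratio 0.4 — a continuous-density simulation cannot plant an exact
dichotomized effect.

**Cell tables** (`simulateCellTables`): Poisson cell counts per
compartment (default 400 per TLS compartment, 800 per stroma compartment,
12 tumours); per cell and marker, Bernoulli positivity at
compartment-specific probabilities and log-normal intensities. The default
positivity matrix encodes the directional biology: every marker enriched
in TLSs over stroma; DC-LAMP ordered IM-TLS-GC (0.20) > CT-TLS-GC (0.12) >
TLS-noGC (0.05) > stroma (0.015); PD-1 and CD20 jointly elevated, and
FOXP3 depressed, in GC-positive TLSs; CD20 slightly higher in CT-TLSs than
IM-TLSs. Default intensity components are well separated (meanlog 2.3 vs
0.0, sdlog 0.3, threshold 3), i.e. idealized unmixing: threshold
phenotyping recovers the planted labels essentially exactly, so
composition tests exercise the statistics, not classifier noise. Real mIF
data have overlapping intensity distributions, spatially correlated cells
and segmentation artefacts; passing tests on these fixtures therefore
demonstrate correctness of the computations and calibration of the
statistics, not robustness to imaging noise.

# What the tests do and do not show

Deterministic operations are validated against brute-force oracles
(running-sum definitions, exhaustive cutpoint scans, hand-evaluated
product-limit estimates, naive agglomeration) and against independent
implementations where one exists (fgsea for the enrichment score, the
survival package's score test against the log-rank statistic). Stochastic
properties are validated as calibration: 95% CI coverage of a planted
hazard ratio across 200 cohorts of n = 300, log-rank type-I error across
2000 null datasets of n = 100, permutation-p uniformity at modest scale.
Problem sizes were chosen so the full suite runs in a few minutes; all
stochastic checks fix their seeds. None of this validates the biology of
any particular cohort: the synthetic generators plant the qualitative
structure the methods are meant to detect, and the tests confirm the
methods detect it.

# Known limitations

* Zone areas are quadrature estimates, not exact polygon-offset areas;
  accuracy is controlled by `gridN` and documented above.
* The DC signature is a placeholder; real analyses must supply published
  lists.
* No competing risks, time-varying covariates or frailty terms in the
  survival layer; no multiple-testing correction across association-table
  rows (deliberately mirroring the analysis style this package supports).
* GeoJSON support covers single-ring Polygon features with role tags, not
  arbitrary geometry collections.
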