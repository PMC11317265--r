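# Synthetic-data generators: determinism, null and noiseless limits,
# planted-structure recovery, and validation errors.

test_that("expression cohort generation is seed-deterministic", {
  cfg <- cohortSimConfig(nSamples = 30, nGenes = 120, seed = 11)
  a <- simulateExpressionCohort(cfg)
  b <- simulateExpressionCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a, "exprs"),
                   SummarizedExperiment::assay(b, "exprs"))
  expect_identical(survivalData(a), survivalData(b))
  expect_identical(latentTruth(a)$latent, latentTruth(b)$latent)
  c2 <- simulateExpressionCohort(cohortSimConfig(nSamples = 30,
                                                 nGenes = 120, seed = 12))
  expect_false(identical(SummarizedExperiment::assay(a, "exprs"),
                         SummarizedExperiment::assay(c2, "exprs")))
})

test_that("null configuration leaves signature genes indistinguishable", {
  cfg <- cohortSimConfig(nSamples = 80, nGenes = 400, latentEffect = 0,
                         logHazardBeta = 0, seed = 21)
  co <- simulateExpressionCohort(cfg)
  X <- SummarizedExperiment::assay(co, "exprs")
  sig <- rownames(X) %in% unlist(cfg$signatures)
  # per-gene z of (mean - baseline-free grand mean); pooled two-sample t
  gene_means <- rowMeans(scale(t(X)))
  p <- t.test(gene_means[sig], gene_means[!sig])$p.value
  expect_gt(p, 0.01)
  # latent and signature expression uncorrelated
  L <- latentTruth(co)$latent
  r <- cor(colMeans(X[sig, ]), L[colnames(X)], method = "spearman")
  expect_lt(abs(r), 0.3)
})

test_that("noiseless limit makes signature genes rank exactly like the latent", {
  cfg <- cohortSimConfig(nSamples = 25, nGenes = 60, latentEffect = 1,
                         noiseSd = 0, seed = 31)
  co <- simulateExpressionCohort(cfg)
  X <- SummarizedExperiment::assay(co, "exprs")
  L <- latentTruth(co)$latent[colnames(X)]
  for (g in intersect(rownames(X), unlist(cfg$signatures))[1:4])
    expect_identical(order(X[g, ]), order(L))
})

test_that("default cohort: signature expression tracks the latent abundance", {
  co <- simulateExpressionCohort(cohortSimConfig(seed = 1))
  X <- SummarizedExperiment::assay(co, "exprs")
  sig <- rownames(X) %in% unlist(tlsSignatureSets())
  L <- latentTruth(co)$latent[colnames(X)]
  expect_gte(cor(colMeans(X[sig, ]), L, method = "spearman"), 0.8)
})

test_that("cohort config validation rejects bad inputs", {
  expect_error(cohortSimConfig(nSamples = 1), "nSamples")
  expect_error(cohortSimConfig(nGenes = 5), "exceed")
  # overlap between signature lists is allowed and recorded
  cfg <- cohortSimConfig(nGenes = 100)
  expect_true("CXCL13" %in% cfg$overlap[["TLS:GC"]])
})

test_that("tissue: zero intensity gives zero events, baseline-only hazard", {
  cfg <- tissueSimConfig(nCases = 3, lambdaCT = 0, lambdaIM = 0,
                         nVertices = 128, seed = 5)
  sim <- simulateTissueCohort(cfg, gridN = 200)
  expect_identical(nrow(sim$events), 0L)
  expect_identical(sim$truth$im_sfl_density, rep(0, 3))
})

test_that("tissue: harmonic-free boundary is an exact circle", {
  cfg <- tissueSimConfig(boundaryHarmonics = list(), meanRadius = 10)
  b <- tumorBoundary(cfg)
  expect_lt(max(abs(sqrt(rowSums(b^2)) - 10)), 1e-9)
})

test_that("folding harmonics are rejected with the harmonic named", {
  expect_error(tissueSimConfig(boundaryHarmonics = list(c(0.2, 2, 0),
                                                        c(0.9, 5, 1))),
               "harmonic 2")
})

test_that("IM event counts match the Poisson mean on a circle", {
  # circle R0 = 10, band 2.5, lambda_IM = 2/mm^2:
  # E[N] = 2 * pi * (12.5^2 - 7.5^2) ~= 628.3
  cfg <- tissueSimConfig(nCases = 200, boundaryHarmonics = list(),
                         lambdaCT = 0, lambdaIM = 2, nVertices = 256,
                         seed = 42)
  sim <- simulateTissueCohort(cfg, gridN = 400)
  counts <- table(factor(sim$events$case_id,
                         levels = unique(sim$survival$id)))
  expected <- 2 * pi * (12.5^2 - 7.5^2)
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # all events generated inside the IM band
  expect_true(all(sim$events$zone == "IM"))
})

test_that("tissue cases are reproducible individually and in the cohort", {
  cfg <- tissueSimConfig(nCases = 4, nVertices = 128, seed = 7)
  sim <- simulateTissueCohort(cfg, gridN = 250)
  single <- simulateTissueCase(cfg, 3L, sim$partition)
  from_cohort <- sim$events[sim$events$case_id == "case_003", ]
  rownames(from_cohort) <- NULL
  rownames(single$events) <- NULL
  expect_identical(single$events, from_cohort)
})

test_that("cell tables: planted positivity fractions are recovered", {
  cfg <- cellSimConfig(nCases = 1,
                       cellCounts = c(CT_stroma = 10000),
                       positivityProbs = matrix(0.5, 1, 6,
                         dimnames = list("CT_stroma", mifPanel())),
                       seed = 9)
  sim <- simulateCellTables(cfg)
  expect_lt(abs(mean(sim$truth[["CD20"]]) - 0.5), 0.02)
  # default intensity components are separated: thresholding recovers truth
  called <- sim$cells[["CD20"]] >= 3
  expect_gt(mean(called == sim$truth[["CD20"]]), 0.999)
})

test_that("zero positivity yields zero positives downstream", {
  cfg <- cellSimConfig(nCases = 1, cellCounts = c(IM_TLS_GC = 300),
                       positivityProbs = matrix(0, 1, 6,
                         dimnames = list("IM_TLS_GC", mifPanel())),
                       seed = 10)
  sim <- simulateCellTables(cfg)
  ph <- phenotypeCells(sim$cells, thresholds = default_mif_thresholds())
  cs <- compositionSummary(ph, "full")
  expect_true(all(cs$percent <= 0.5))   # only rare negative-tail crossings
  expect_true(all(!sim$truth))
})

test_that("unknown compartments and markers are rejected", {
  expect_error(cellSimConfig(cellCounts = c(weird = 10)), "compartment")
  expect_error(cellSimConfig(positivityProbs = matrix(0.5, 1, 1,
    dimnames = list("CT_stroma", "KI67"))), "marker")
})

test_that("two-group survival generator plants the requested hazard ratio", {
  d <- simulateSurvivalCohort(n = 4000, hr = 0.4, seed = 13)
  fit <- coxFit(transform(d, high = as.integer(group == "high")), "high")
  expect_lt(abs(fit$beta - log(0.4)), 0.15)
  expect_true(all(d$time_months > 0))
})
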