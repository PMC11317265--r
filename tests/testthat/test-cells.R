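# mIF phenotyping, composition percentages, percent-intensity correlation
# and co-infiltration clustering.

make_cells <- function(intensities, case_id = "t1", region = "CT",
                       context = "stroma") {
  n <- nrow(intensities)
  data.frame(case_id = case_id, x_mm = runif(n), y_mm = runif(n),
             compartment_region = region, compartment_context = context,
             intensities, stringsAsFactors = FALSE, check.names = FALSE)
}

zero_cells <- function(n = 10) {
  m <- matrix(0, n, 6, dimnames = list(NULL, mifPanel()))
  make_cells(as.data.frame(m, check.names = FALSE))
}

test_that("zero intensities produce no positives", {
  ph <- phenotypeCells(zero_cells(), thresholds = default_mif_thresholds())
  for (p in attr(ph, "phenotypes")) expect_true(all(!ph[[p]]))
})

test_that("a separable mixture recovers planted labels exactly", {
  sim <- simulateCellTables(cellSimConfig(
    nCases = 1, cellCounts = c(IM_TLS_GC = 2000),
    intensityPos = c(meanlog = 4, sdlog = 0.1),
    intensityNeg = c(meanlog = 0, sdlog = 0.1), seed = 3))
  ph <- phenotypeCells(sim$cells, thresholds = default_mif_thresholds())
  for (m in mifPanel())
    expect_identical(unname(ph[[paste0(m, "+")]]), sim$truth[[m]])
})

test_that("a 12-cell worked table matches hand evaluation", {
  inten <- data.frame(
    CD20 = c(5, 1, 4, 0, 9, 2, 3, 3, 0, 7, 1, 6),
    CD8 = c(0, 6, 1, 5, 0, 4, 2, 9, 1, 0, 8, 2),
    FOXP3 = c(0, 0, 5, 4, 1, 0, 0, 6, 2, 1, 5, 0),
    CD23 = c(4, 0, 1, 0, 6, 1, 0, 2, 0, 5, 1, 1),
    "DC-LAMP" = c(0, 1, 0, 2, 0, 6, 5, 0, 1, 0, 2, 4),
    "PD-1" = c(6, 2, 5, 1, 7, 0, 1, 4, 0, 6, 3, 2),
    check.names = FALSE)
  ph <- phenotypeCells(make_cells(inten),
                       thresholds = default_mif_thresholds())
  expect_identical(ph[["CD20+"]], inten$CD20 >= 3)
  expect_identical(ph[["PD1+CD20+"]],
                   inten$CD20 >= 3 & inten[["PD-1"]] >= 3)
  expect_identical(ph[["FOXP3+CD8+"]],
                   inten$FOXP3 >= 3 & inten$CD8 >= 3)
})

test_that("phenotyping is monotone in the threshold", {
  set.seed(19)
  m <- matrix(rlnorm(600), 100, 6, dimnames = list(NULL, mifPanel()))
  cells <- make_cells(as.data.frame(m, check.names = FALSE))
  counts <- vapply(c(0.5, 1, 2, 4), function(tau) {
    th <- setNames(rep(tau, 6), mifPanel())
    sum(phenotypeCells(cells, thresholds = th)[["CD8+"]])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rules referencing unknown markers are rejected", {
  expect_error(phenotypeRule("bad", c("CD20", "KI67")), "KI67")
  expect_error(phenotypeCells(zero_cells(),
                              thresholds = c(CD20 = 1)), "threshold")
})

test_that("composition percentages use the compartment denominator", {
  inten <- as.data.frame(matrix(0, 10, 6,
                                dimnames = list(NULL, mifPanel())),
                         check.names = FALSE)
  inten$CD8[1:2] <- 5
  ph <- phenotypeCells(make_cells(inten),
                       thresholds = default_mif_thresholds())
  cs <- compositionSummary(ph, "full")
  expect_equal(cs$percent[cs$phenotype == "CD8+"], 20)
})

test_that("pooling compartments is count-weighted, not averaged", {
  a <- as.data.frame(matrix(0, 10, 6, dimnames = list(NULL, mifPanel())),
                     check.names = FALSE)
  b <- a
  a$CD8[1:2] <- 5   # 2/10 in IM TLS
  b$CD8[1:3] <- 5   # 3/10 in CT TLS
  cells <- rbind(make_cells(a, region = "IM", context = "TLS_GC"),
                 make_cells(b, region = "CT", context = "TLS_GC"))
  ph <- phenotypeCells(cells, thresholds = default_mif_thresholds())
  cs <- compositionSummary(ph, "TLS_vs_stroma")
  expect_equal(cs$percent[cs$phenotype == "CD8+" & cs$compartment == "TLS"],
               25)   # 5/20, not mean(20%, 30%)
})

test_that("mutually exclusive exhaustive phenotypes sum to 100 percent", {
  inten <- as.data.frame(matrix(0, 40, 6, dimnames = list(NULL, mifPanel())),
                         check.names = FALSE)
  half <- sample(40, 20)
  inten$CD20[half] <- 5
  inten$CD8[setdiff(1:40, half)] <- 5
  ph <- phenotypeCells(make_cells(inten),
                       thresholds = default_mif_thresholds())
  cs <- compositionSummary(ph, "full")
  tot <- sum(cs$percent[cs$phenotype %in% c("CD20+", "CD8+")])
  expect_equal(tot, 100, tolerance = 1e-9)
})

test_that("percent-intensity correlation: affine case and formula oracle", {
  set.seed(27)
  blocks <- lapply(1:5, function(i) {
    n <- 100
    inten <- as.data.frame(matrix(0.1, n, 6,
                                  dimnames = list(NULL, mifPanel())),
                           check.names = FALSE)
    npos <- 10 * i
    inten$CD20[seq_len(npos)] <- 4 + 0.2 * i   # intensity affine in percent
    make_cells(inten, case_id = paste0("t", i))
  })
  ph <- phenotypeCells(do.call(rbind, blocks),
                       thresholds = default_mif_thresholds())
  r <- intensityPercentCorrelation(ph, markers = "CD20")
  expect_equal(r$r, 1, tolerance = 1e-9)

  # 5-case toy equals the direct Pearson formula
  pct <- c(10, 20, 30, 40, 50)
  mfi <- vapply(1:5, function(i)
    mean(ph[["CD20"]][ph$case_id == paste0("t", i) & ph[["CD20+"]]]),
    numeric(1))
  direct <- sum((pct - mean(pct)) * (mfi - mean(mfi))) /
    sqrt(sum((pct - mean(pct))^2) * sum((mfi - mean(mfi))^2))
  expect_equal(r$r, direct, tolerance = 1e-9)
})

test_that("clustering: identical rows merge first at height zero", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  cl <- coinfiltrationCluster(m)
  expect_equal(cl$hclust$height[1], 0)
  expect_setequal(cl$hclust$labels[-cl$hclust$merge[1, ]], c("a", "b"))
})

test_that("clustering: forced topology and the naive agglomeration oracle", {
  m3 <- rbind(r1 = c(0, 0), r2 = c(1, 0), r3 = c(10, 0))
  cl3 <- coinfiltrationCluster(m3)
  expect_setequal(cl3$hclust$labels[-cl3$hclust$merge[1, ]], c("r1", "r2"))

  set.seed(33)
  m8 <- matrix(rnorm(8 * 4), 8, 4,
               dimnames = list(paste0("row", 1:8), NULL))
  cl8 <- coinfiltrationCluster(m8)
  want <- oracle_average_linkage(m8)
  expect_equal(sort(cl8$hclust$height), sort(want$heights),
               tolerance = 1e-10)
  # merge member sets coincide step by step
  got_members <- lapply(seq_len(7), function(i) {
    collect <- function(j)
      if (j < 0) -j else unlist(lapply(cl8$hclust$merge[j, ], collect))
    sort(collect(i))
  })
  expect_identical(got_members, want$merges)
})

test_that("rows with missing frequencies are named in the error", {
  m <- rbind(ok = c(1, 2), bad = c(NA, 1), other = c(0, 0))
  expect_error(coinfiltrationCluster(m), "bad")
})
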