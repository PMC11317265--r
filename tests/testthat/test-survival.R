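# Kaplan-Meier, log-rank, Cox and maximally selected rank statistics, each
# validated against hand evaluation or a brute-force oracle.

test_that("product-limit estimate matches hand evaluation", {
  km <- kmEstimate(c(5, 8, 12), c(1, 0, 1))
  expect_equal(km$time, c(5, 12))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$at_risk, c(3, 1))
})

test_that("all-censored data keeps survival at one", {
  km <- kmEstimate(c(3, 6, 9), c(0, 0, 0))
  expect_identical(nrow(km), 0L)   # no event times; S(t) = 1 throughout
})

test_that("replicating every record leaves the estimate unchanged", {
  tm <- c(2, 4, 4, 7, 9); ev <- c(1, 0, 1, 1, 0)
  a <- kmEstimate(tm, ev)
  b <- kmEstimate(rep(tm, 2), rep(ev, 2))
  expect_equal(a$time, b$time)
  expect_equal(a$survival, b$survival)
})

test_that("log-rank: symmetry, df, and the O-E oracle", {
  tm <- c(2, 4, 5, 7); ev <- c(1, 0, 1, 1)
  sym <- logrankTest(rep(tm, 2), rep(ev, 2), rep(c("a", "b"), each = 4))
  expect_equal(sym$chi2, 0, tolerance = 1e-12)
  expect_equal(sym$p.value, 1)

  three <- logrankTest(c(tm, tm + 1, tm + 2), rep(ev, 3),
                       rep(c("a", "b", "c"), each = 4))
  expect_identical(three$df, 2L)

  tm8 <- c(1, 3, 4, 6, 2, 5, 8, 9); ev8 <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g8 <- rep(c("x", "y"), each = 4)
  got <- logrankTest(tm8, ev8, g8)
  want <- oracle_logrank_chi2(tm8, ev8, g8)
  expect_equal(got$chi2, want$chi2, tolerance = 1e-10)
})

test_that("non-positive times are rejected", {
  expect_error(kmEstimate(c(0, 2), c(1, 1)), "positive")
  expect_error(logrankTest(c(-1, 2), c(1, 1), c("a", "b")), "positive")
})

test_that("Cox beta is zero for symmetric groups", {
  tm <- c(2, 5, 7, 2, 5, 7); ev <- c(1, 1, 0, 1, 1, 0)
  d <- data.frame(time_months = tm, event = ev, g = rep(0:1, each = 3))
  fit <- coxFit(d, "g")
  expect_equal(fit$beta, 0, tolerance = 1e-9)
})

test_that("Cox estimate matches brute-force partial-likelihood maximization", {
  d <- data.frame(time_months = c(1.3, 2.1, 3.4, 4.8, 6.2, 7.7),
                  event = c(1, 1, 0, 1, 1, 1),
                  g = c(1, 0, 1, 0, 1, 0))
  fit <- coxFit(d, "g")
  opt <- optimize(function(b)
    -oracle_cox_loglik(b, d$time_months, d$event, d$g), c(-5, 5),
    tol = 1e-10)
  expect_equal(fit$beta, opt$minimum, tolerance = 1e-6)
})

test_that("Cox score test at beta=0 equals the log-rank statistic", {
  set.seed(41)
  tm <- round(rexp(40, 0.1), 6)   # continuous: no ties
  ev <- rbinom(40, 1, 0.8)
  g <- rep(0:1, each = 20)
  lr <- logrankTest(tm, ev, g)
  sc <- survival::coxph(survival::Surv(tm, ev) ~ g)$score
  expect_equal(lr$chi2, sc, tolerance = 1e-8)
})

test_that("Cox input validation and separation flagging", {
  d <- data.frame(time_months = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                  g = c(0, 0, 1, 1))
  expect_error(coxFit(d, "nope"), "not in data")
  expect_error(coxFit(transform(d, g = 1), "g"), "constant")
  expect_error(coxFit(transform(d, event = 0), "g"), "at least one event")
  # perfect separation: all early events in one group
  d2 <- data.frame(time_months = c(1, 2, 3, 10, 11, 12),
                   event = rep(1, 6), g = rep(c(1, 0), each = 3))
  expect_warning(fit <- coxFit(d2, "g"), "separation")
  expect_true(fit$separation)
})

test_that("maxstat equals the exhaustive-scan oracle", {
  set.seed(52)
  n <- 50
  x <- rnorm(n)
  tm <- rexp(n, 0.08 * exp(0.6 * (x > 0.3)))
  ev <- as.integer(tm < 25); tm <- pmin(tm, 25)
  got <- maxstatCutpoint(x, tm, ev, pMethod = "none")
  want <- oracle_maxstat(x, tm, ev)
  expect_equal(got$cutpoint, want$cutpoint)
  expect_equal(got$statistic, want$M, tolerance = 1e-10)
  expect_equal(abs(got$stats), abs(want$stats), tolerance = 1e-10)
})

test_that("perfect separation drives the permutation p to its floor", {
  # all events (tied, early) cluster at low x, late censorings at high x:
  # only the gap split separates outcomes, so the scan must choose it
  set.seed(3)
  x <- c(runif(15, 0, 1), runif(15, 100, 101))
  tm <- c(rep(1, 15), rep(200, 15))
  ev <- c(rep(1, 15), rep(0, 15))
  ms <- maxstatCutpoint(x, tm, ev, nPerm = 499, seed = 3)
  expect_gt(ms$cutpoint, 1); expect_lt(ms$cutpoint, 100)
  expect_equal(ms$p, 1 / 500, tolerance = 1e-12)
})

test_that("two-group log-rank chi2 is the square of the maxstat statistic", {
  set.seed(63)
  x <- rnorm(30); tm <- rexp(30, 0.1); ev <- rbinom(30, 1, 0.7)
  ev[1] <- 1L
  ms <- maxstatCutpoint(x, tm, ev, pMethod = "none")
  cut <- ms$cutpoint
  lr <- logrankTest(tm, ev, as.integer(x > cut))
  i <- which(ms$candidates == cut)
  expect_equal(lr$chi2, ms$stats[i]^2, tolerance = 1e-8)
})

test_that("constant x has no admissible cutpoint", {
  expect_error(maxstatCutpoint(rep(1, 10), rexp(10, 1), rep(1, 10)),
               "no admissible|constant")
})

test_that("Lausen-Schumacher approximation is a sane p-value", {
  set.seed(71)
  x <- rnorm(80); tm <- rexp(80, 0.1); ev <- rep(1L, 80)
  ms <- maxstatCutpoint(x, tm, ev, pMethod = "approximation")
  expect_gte(ms$p, 0); expect_lte(ms$p, 1)
})
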