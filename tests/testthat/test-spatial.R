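# CT/IM partition geometry, zone assignment, maturation staging and the six
# TLS scores.

test_that("circle partition areas match the analytic annulus", {
  zp <- buildZones(circle_polygon(10, 512), bandWidth = 2.5)
  expect_lt(abs(areaCT(zp) - pi * 7.5^2) / (pi * 7.5^2), 0.005)
  expect_lt(abs(areaIM(zp) - pi * (12.5^2 - 7.5^2)) /
              (pi * (12.5^2 - 7.5^2)), 0.005)
})

test_that("a tumour thinner than twice the band has an empty CT", {
  zp <- suppressWarnings(buildZones(circle_polygon(2, 64), bandWidth = 2.5))
  expect_identical(areaCT(zp), 0)
  expect_gt(areaIM(zp), 0)
})

test_that("self-intersecting boundaries are rejected", {
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(buildZones(bow, 0.5), "self-intersecting")
})

test_that("zone assignment matches analytic distances on the circle", {
  zp <- buildZones(circle_polygon(10, 512), bandWidth = 2.5)
  z <- assignZone(c(5, 9, 11, 13.1, 7.5), rep(0, 5), zp)
  expect_identical(as.character(z), c("CT", "IM", "IM", "outside", "IM"))
})

test_that("zone labels agree with a brute-force distance oracle", {
  set.seed(12)
  poly <- {
    th <- sort(runif(40, 0, 2 * pi))
    r <- 8 + 2 * sin(3 * th) + rnorm(40, 0, 0.2)
    cbind(r * cos(th), r * sin(th))
  }
  zp <- suppressWarnings(buildZones(poly, bandWidth = 2))
  px <- runif(1000, -12, 12); py <- runif(1000, -12, 12)
  # oracle: min distance over all boundary segments, crossing-count inside
  seg_dist <- function(x, y) {
    n <- nrow(poly)
    best <- Inf
    for (i in seq_len(n)) {
      a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
      ab <- b - a
      t <- max(0, min(1, sum((c(x, y) - a) * ab) / sum(ab^2)))
      best <- min(best, sqrt(sum((c(x, y) - a - t * ab)^2)))
    }
    best
  }
  d_oracle <- mapply(seg_dist, px, py)
  expect_equal(distanceToBoundary(px, py, poly), d_oracle,
               tolerance = 1e-12)
  got <- assignZone(px, py, zp)
  inside <- pointInPolygon(px, py, poly)
  want <- ifelse(d_oracle <= 2, "IM", ifelse(inside, "CT", "outside"))
  expect_identical(as.character(got), want)
})

test_that("grid areas agree with a Monte-Carlo point-sampling oracle", {
  set.seed(23)
  th <- seq(0, 2 * pi, length.out = 193)[-193]
  r <- 9 * (1 + 0.15 * cos(4 * th) + 0.05 * cos(7 * th + 1))
  poly <- cbind(r * cos(th), r * sin(th))
  band <- 2.5
  zp <- buildZones(poly, band)
  n <- 1e5
  xr <- range(poly[, 1]) + c(-1, 1) * band
  yr <- range(poly[, 2]) + c(-1, 1) * band
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  z <- assignZone(px, py, zp)
  box <- diff(xr) * diff(yr)
  mc_ct <- box * mean(z == "CT"); mc_im <- box * mean(z == "IM")
  expect_lt(abs(mc_ct - areaCT(zp)) / areaCT(zp), 0.02)
  expect_lt(abs(mc_im - areaIM(zp)) / areaIM(zp), 0.02)
  # partition: every interior point is CT or IM, never both (single label)
  expect_true(all(z[pointInPolygon(px, py, poly)] %in% c("CT", "IM")))
})

test_that("IM area shrinks monotonically with the band width", {
  areas <- vapply(c(2.5, 1, 0.1), function(b)
    areaIM(buildZones(circle_polygon(10, 256), b)), numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("maturation staging follows the FDC/GC flags", {
  got <- classifyMaturation(c(FALSE, TRUE, FALSE, TRUE),
                            c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(as.character(got),
                   c("E-TLS", "PFL-TLS", "SFL-TLS", "SFL-TLS"))
})

fake_partition <- function(area_ct = 10, area_im = 5) {
  methods::new("ZonePartition",
               boundary = circle_polygon(3, 16), tissueExtent = NULL,
               bandWidth = 1, areaCT = area_ct, areaIM = area_im,
               gridSpacing = 0.1, metadata = list())
}

test_that("score arithmetic follows the six definitions", {
  zp <- fake_partition()
  ev <- data.frame(case_id = "c1",
                   x_mm = rep(0, 5), y_mm = rep(0, 5),
                   maturation = c("E-TLS", "SFL-TLS", "PFL-TLS",
                                  "SFL-TLS", "E-TLS"),
                   zone = c("CT", "CT", "CT", "IM", "IM"))
  sc <- scoreTable(computeTLSScores(ev, zp))
  expect_equal(sc$CT_TLS_N, 3)
  expect_equal(sc$IM_TLS_N, 2)
  expect_equal(sc$Total_TLS_N, 5)
  expect_equal(sc$CT_TLS_D, 0.3)
  expect_equal(sc$IM_TLS_D, 0.4)
  expect_equal(sc$Total_TLS_D, 5 / 15)
  # GC-restricted variants count only SFL events
  expect_equal(sc$CT_TLS_N_GC, 1)
  expect_equal(sc$IM_TLS_N_GC, 1)
  sc2 <- scoreTable(computeTLSScores(ev, zp, subset = "GC_only"))
  expect_equal(sc2$Total_TLS_N, 2)
})

test_that("no events gives zero counts and densities", {
  sc <- scoreTable(computeTLSScores(data.frame(), fake_partition()))
  expect_true(all(sc[, -1] == 0))
})

test_that("outside events are excluded with a message", {
  zp <- fake_partition()
  ev <- data.frame(case_id = "c1", x_mm = 0, y_mm = 0,
                   maturation = "E-TLS", zone = "outside")
  expect_message(res <- computeTLSScores(ev, zp), "outside")
  expect_identical(res@excluded, 1L)
  expect_equal(scoreTable(res)$Total_TLS_N, 0)
})

test_that("score additivity holds on random fixtures", {
  set.seed(31)
  zp <- fake_partition(12, 7)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    ev <- data.frame(case_id = sample(c("a", "b"), n, TRUE),
                     x_mm = 0, y_mm = 0,
                     maturation = sample(c("E-TLS", "PFL-TLS", "SFL-TLS"),
                                         n, TRUE),
                     zone = sample(c("CT", "IM"), n, TRUE))
    sc <- scoreTable(computeTLSScores(ev, zp))
    expect_equal(sc$Total_TLS_N, sc$CT_TLS_N + sc$IM_TLS_N)
    expect_equal(sc$Total_TLS_N_GC, sc$CT_TLS_N_GC + sc$IM_TLS_N_GC)
  }
})

test_that("empirical IM density converges to the configured intensity", {
  cfg <- tissueSimConfig(nCases = 200, boundaryHarmonics = list(),
                         lambdaCT = 0.3, lambdaIM = 0.5, nVertices = 192,
                         seed = 77)
  sim <- simulateTissueCohort(cfg, gridN = 300)
  sc <- scoreTable(computeTLSScores(sim$events, sim$partition))
  expect_lt(abs(mean(sc$IM_TLS_D) - 0.5) / 0.5, 0.05)
  expect_lt(abs(mean(sc$CT_TLS_D) - 0.3) / 0.3, 0.05)
})
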