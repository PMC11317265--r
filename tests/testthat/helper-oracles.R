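# Independent brute-force oracles used to validate the package's
# implementations. These deliberately re-derive each quantity from its
# definition, sharing no code with the package internals.

# ssGSEA score by direct evaluation of the running-sum definition:
# genes ranked by decreasing expression (ties by symbol), rank statistic
# N..1, in-set increments |rank|^alpha normalized within the set,
# out-of-set decrements 1/(N - |S|), score = sum of running sums.
oracle_ssgsea <- function(x, genes, set, alpha) {
  N <- length(x)
  ord <- order(-x, genes)
  g_sorted <- genes[ord]
  rank_stat <- N:1
  in_set <- g_sorted %in% set
  m <- sum(in_set)
  w <- rank_stat^alpha
  rs <- 0; total <- 0
  denom <- sum(w[in_set])
  for (i in seq_len(N)) {
    rs <- rs + if (in_set[i]) w[i] / denom else -1 / (N - m)
    total <- total + rs
  }
  total
}

# weighted-KS enrichment score (weight exponent 1) by direct walk
oracle_gsea_es <- function(stat_sorted, in_set) {
  N <- length(stat_sorted)
  m <- sum(in_set)
  denom <- sum(abs(stat_sorted[in_set]))
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (in_set[i]) abs(stat_sorted[i]) / denom else -1 / (N - m)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# signal-to-noise ranking statistic (sd floored at max(0.2|mu|, eps))
oracle_s2n <- function(X, pos) {
  apply(X, 1, function(v) {
    m1 <- mean(v[pos]); m2 <- mean(v[!pos])
    s1 <- max(sd(v[pos]), 0.2 * abs(m1), 1e-8)
    s2 <- max(sd(v[!pos]), 0.2 * abs(m2), 1e-8)
    (m1 - m2) / (s1 + s2)
  })
}

# observed-minus-expected log-rank by direct summation over event times
oracle_logrank_chi2 <- function(time, event, group) {
  group <- as.integer(as.factor(group)) - 1L   # two groups: 0/1
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(U = U, V = V, chi2 = U^2 / V, standardized = U / sqrt(V))
}

# exhaustive maxstat scan: every admissible midpoint cutpoint, standardized
# log-rank statistic per cut, argmax of |statistic| (smallest on ties)
oracle_maxstat <- function(x, time, event, minprop = 0.1) {
  ux <- sort(unique(x))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  keep <- vapply(mids, function(m) {
    p <- mean(x <= m); p >= minprop && p <= 1 - minprop
  }, logical(1))
  cands <- mids[keep]
  stats <- vapply(cands, function(cut)
    oracle_logrank_chi2(time, event, as.integer(x > cut))$standardized,
    numeric(1))
  i <- which.max(abs(stats))
  list(cutpoint = cands[i], M = abs(stats[i]), cands = cands,
       stats = stats)
}

# Cox partial log-likelihood for one covariate, Breslow form (no ties in
# the fixtures it is used on, where Breslow = Efron = exact)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# naive O(n^3) average-linkage agglomeration; returns the merge heights in
# order and the member sets merged at each step
oracle_average_linkage <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- lapply(seq_len(nrow(mat)), identity)
  heights <- numeric(0); merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# minimal circle-boundary polygon used across geometry tests
circle_polygon <- function(R = 10, n = 512L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(R * cos(th), R * sin(th))
}

default_mif_thresholds <- function()
  c("CD20" = 3, "CD8" = 3, "FOXP3" = 3, "CD23" = 3, "DC-LAMP" = 3,
    "PD-1" = 3)
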