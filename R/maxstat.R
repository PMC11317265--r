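# Maximally selected rank statistics: the optimal survival cutpoint for a
# continuous marker, with multiplicity-aware p-values by permutation
# (default) or the Lausen-Schumacher normal approximation.

#' Optimal cutpoint by maximally selected log-rank statistics
#'
#' Candidate cutpoints are the midpoints between consecutive distinct values
#' of \code{x} whose induced split leaves at least a \code{minprop} fraction
#' of subjects on each side. For each candidate the standardized two-group
#' log-rank statistic (group = \code{x > cut}) is computed; the selected
#' cutpoint maximizes its absolute value (exact ties resolved to the
#' smallest candidate). The p-value accounts for the maximal selection:
#' by default, \code{x} is permuted across subjects \code{nPerm} times and
#' \code{p = (1 + #permutations with M* >= M) / (nPerm + 1)}; alternatively
#' the Lausen-Schumacher (1992) improved-Bonferroni approximation is used.
#'
#' @param x continuous marker, one value per subject
#' @param time,event survival outcome (months; 0/1)
#' @param minprop minimum group fraction on each side (default 0.1)
#' @param pMethod "permutation" (default), "approximation", or "none"
#' @param nPerm permutations for \code{pMethod = "permutation"}
#' @param seed RNG seed for the permutations
#' @return list of class \code{maxstat_result}: \code{cutpoint},
#'   \code{statistic} (M, the maximal standardized statistic), \code{p},
#'   \code{candidates}, \code{stats} (the standardized statistic at each
#'   candidate), \code{minprop}, \code{p_method}, \code{n_perm}
#' @examples
#' set.seed(1)
#' x <- rnorm(60)
#' tm <- rexp(60, exp(-0.8 * (x > 0)))
#' maxstatCutpoint(x, tm, rep(1, 60), pMethod = "none")
#' @export
maxstatCutpoint <- function(x, time, event, minprop = 0.1,
                            pMethod = c("permutation", "approximation",
                                        "none"),
                            nPerm = 1000L, seed = NULL) {
  pMethod <- match.arg(pMethod)
  .check_surv(time, event)
  if (length(x) != length(time)) stop("x and survival lengths differ")
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must be in (0, 0.5)")
  ux <- sort(unique(x))
  if (length(ux) < 2L) stop("constant x: no admissible cutpoint")
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  prop_below <- vapply(mids, function(m) mean(x <= m), numeric(1))
  keep <- prop_below >= minprop & prop_below <= 1 - minprop
  cands <- mids[keep]
  if (!length(cands))
    stop("no admissible cutpoint inside the [minprop, 1-minprop] window")

  ord <- order(time)
  ts <- as.numeric(time[ord])
  ev <- as.integer(event[ord])
  xs <- as.numeric(x[ord])
  stats <- cpp_maxstat_scan(xs, ts, ev, cands)
  i_best <- which.max(abs(stats))            # which.max: first (smallest) tie
  M <- abs(stats[i_best])

  p <- switch(pMethod,
    none = NA_real_,
    permutation = .with_seed(seed, {
      cnt <- cpp_maxstat_perm_count(xs, ts, ev, cands, as.integer(nPerm), M)
      (1 + cnt) / (nPerm + 1)
    }),
    approximation = {
      b <- M
      q1 <- minprop; q2 <- 1 - minprop
      pv <- dnorm(b) * ((b - 1 / b) *
                          log((q2 * (1 - q1)) / (q1 * (1 - q2))) + 4 / b)
      min(1, max(0, pv))
    })

  structure(list(cutpoint = cands[i_best], statistic = M, p = p,
                 candidates = cands, stats = stats, minprop = minprop,
                 p_method = pMethod,
                 n_perm = if (pMethod == "permutation") nPerm else NA_integer_),
            class = "maxstat_result")
}

#' @export
print.maxstat_result <- function(x, ...) {
  cat("Maximally selected log-rank statistic\n")
  cat(sprintf("  cutpoint: %.6g  M: %.4f  p (%s): %s\n", x$cutpoint,
              x$statistic, x$p_method,
              ifelse(is.na(x$p), "-", format.pval(x$p))))
  cat(sprintf("  %d candidate cutpoints, minprop %.2f\n",
              length(x$candidates), x$minprop))
  invisible(x)
}
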