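# Association and comparison statistics used across the cohort analyses:
# chi-square and Fisher tests on contingency tables, rank/linear
# correlation, and two-/multi-group location tests.

.check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2 x 2")
  if (sum(tab) == 0) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row/column margin")
  tab
}

#' Pearson chi-square test of independence
#'
#' Uncorrected by default: the continuity correction is off unless requested
#' (and applies to 2 x 2 tables only). A structured warning records expected
#' counts below 5.
#'
#' @param tab r x c matrix of non-negative integer counts (r, c >= 2)
#' @param correction apply the Yates continuity correction (2 x 2 only)
#' @return list: method, statistic, df, p.value, expected, warnings
#' @examples
#' chiSquareTest(matrix(c(32, 12, 105, 17), 2))
#' @export
chiSquareTest <- function(tab, correction = FALSE) {
  tab <- .check_table(tab)
  res <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  warn <- character()
  if (any(res$expected < 5))
    warn <- c(warn, sprintf("%d cell(s) with expected count < 5",
                            sum(res$expected < 5)))
  list(method = if (correction) "chi-square (Yates)" else "chi-square",
       statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = unname(res$p.value), expected = res$expected,
       warnings = warn)
}

#' Fisher exact test on a 2 x 2 table
#'
#' Two-sided by the probability-ordering rule (tables whose hypergeometric
#' probability does not exceed that of the observed table).
#'
#' @param tab 2 x 2 matrix of counts
#' @return list: method, p.value, odds_ratio
#' @examples fisherExactTest(matrix(c(5, 0, 0, 5), 2))
#' @export
fisherExactTest <- function(tab) {
  tab <- .check_table(tab)
  if (nrow(tab) != 2L || ncol(tab) != 2L)
    stop("Fisher exact test requires a 2 x 2 table")
  res <- stats::fisher.test(tab)
  list(method = "fisher", p.value = unname(res$p.value),
       odds_ratio = unname(res$estimate))
}

#' Correlation test
#'
#' Pearson, or Spearman (Pearson on tie-averaged ranks) with the two-sided
#' t-approximation p-value.
#'
#' @param x,y numeric vectors, n >= 3, finite
#' @param method "spearman" or "pearson"
#' @return list: method, r, p.value, n
#' @export
correlationTest <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  res <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(method = method, r = unname(res$estimate),
       p.value = unname(res$p.value), n = length(x))
}

#' Two- and multi-group location comparison
#'
#' Classical equal-variance two-tailed t test, one-way ANOVA (F with df
#' (k - 1, N - k)), or the Wilcoxon rank-sum test (exact enumeration when
#' both groups have n <= 10 and there are no ties; tie-corrected normal
#' approximation otherwise).
#'
#' @param values numeric vector of observations
#' @param group group membership, same length
#' @param method "t_two_tailed", "anova_oneway" or "wilcoxon_ranksum"
#' @return list: method, statistic, df (when defined), p.value
#' @examples
#' groupCompare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
#'              method = "wilcoxon_ranksum")
#' @export
groupCompare <- function(values, group,
                         method = c("t_two_tailed", "anova_oneway",
                                    "wilcoxon_ranksum")) {
  method <- match.arg(method)
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (method == "anova_oneway" && k < 2L) stop("ANOVA needs >= 2 groups")
  if (method != "anova_oneway" && k != 2L)
    stop(method, " needs exactly 2 groups")
  split_vals <- split(values, group)
  if (method == "t_two_tailed") {
    if (any(lengths(split_vals) < 2L)) stop("t test needs n >= 2 per group")
    res <- stats::t.test(split_vals[[1]], split_vals[[2]],
                         var.equal = TRUE)
    list(method = "t (two-tailed, equal variance)",
         statistic = unname(res$statistic), df = unname(res$parameter),
         p.value = res$p.value)
  } else if (method == "anova_oneway") {
    if (any(lengths(split_vals) < 2L)) stop("ANOVA needs n >= 2 per group")
    fit <- stats::aov(values ~ group)
    tab <- summary(fit)[[1]]
    list(method = "one-way ANOVA", statistic = tab[1, "F value"],
         df = c(tab[1, "Df"], tab[2, "Df"]), p.value = tab[1, "Pr(>F)"])
  } else {
    n1 <- length(split_vals[[1]]); n2 <- length(split_vals[[2]])
    exact <- n1 <= 10L && n2 <= 10L && !anyDuplicated(values)
    res <- suppressWarnings(
      stats::wilcox.test(split_vals[[1]], split_vals[[2]],
                         exact = exact, correct = !exact))
    list(method = if (exact) "wilcoxon (exact)" else "wilcoxon (normal approx.)",
         statistic = unname(res$statistic), df = NA_real_,
         p.value = res$p.value)
  }
}

#' Clinicopathological association table
#'
#' Builds, per variable, the contingency table of the variable against a
#' two-level grouping (e.g. low/high TLS density) and tests independence:
#' uncorrected Pearson chi-square by default, substituting the Fisher exact
#' test for 2 x 2 tables with any expected count below 5 (the sparse-cell
#' regime where the chi-square approximation is unreliable). Star
#' annotations follow the *, **, ***, **** convention.
#'
#' @param clinical data.frame of per-case categorical variables
#' @param groupVar name of the two-level grouping column
#' @param vars variable names to test (default: all others)
#' @return data.frame: variable, method, statistic, p, stars
#' @export
associationTable <- function(clinical, groupVar,
                             vars = setdiff(colnames(clinical), groupVar)) {
  if (!groupVar %in% colnames(clinical)) stop("missing column: ", groupVar)
  g <- as.factor(clinical[[groupVar]])
  rows <- lapply(vars, function(v) {
    tab <- table(clinical[[v]], g)
    res <- tryCatch({
      ct <- chiSquareTest(tab)
      if (all(dim(tab) == 2L) && length(ct$warnings))
        fisherExactTest(tab)
      else ct
    }, error = function(e)
      list(method = "not testable", statistic = NA_real_,
           p.value = NA_real_))
    data.frame(variable = v, method = res$method,
               statistic = if (is.null(res$statistic)) NA_real_
                           else res$statistic,
               p = res$p.value, stars = pStars(res$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
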