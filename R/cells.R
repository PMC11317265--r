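# mIF cell-composition module: marker thresholding / phenotype calling,
# per-compartment composition percentages, percent-intensity correlation,
# and co-infiltration clustering.

#' The six-marker mIF panel
#' @return character vector of marker names
#' @export
mifPanel <- function() .mif_markers

#' Define a phenotype rule
#'
#' A phenotype is a conjunction of marker positivity predicates, e.g.
#' PD-1+CD20+ cells are positive for both PD-1 and CD20 at their respective
#' thresholds.
#'
#' @param name phenotype label
#' @param markers markers entering the conjunction (panel members)
#' @return list of class \code{phenotype_rule}
#' @examples phenotypeRule("PD1+CD20+", c("PD-1", "CD20"))
#' @export
phenotypeRule <- function(name, markers) {
  unknown <- setdiff(markers, .mif_markers)
  if (length(unknown))
    stop("unknown marker(s) in rule '", name, "': ",
         paste(unknown, collapse = ", "))
  structure(list(name = name, markers = markers), class = "phenotype_rule")
}

#' Default phenotype rules
#'
#' Single-marker positivity for each panel member plus the four
#' co-expression phenotypes used for co-infiltration analysis: PD1+CD20+,
#' FOXP3+CD8+, PD1+CD8+ and PD1+FOXP3+.
#'
#' @return named list of \code{\link{phenotypeRule}}s
#' @export
defaultPhenotypeRules <- function() {
  singles <- lapply(.mif_markers, function(m)
    phenotypeRule(paste0(m, "+"), m))
  names(singles) <- paste0(.mif_markers, "+")
  co <- list(
    "PD1+CD20+" = phenotypeRule("PD1+CD20+", c("PD-1", "CD20")),
    "FOXP3+CD8+" = phenotypeRule("FOXP3+CD8+", c("FOXP3", "CD8")),
    "PD1+CD8+" = phenotypeRule("PD1+CD8+", c("PD-1", "CD8")),
    "PD1+FOXP3+" = phenotypeRule("PD1+FOXP3+", c("PD-1", "FOXP3")))
  c(singles, co)
}

#' Otsu threshold of a 1-D intensity distribution
#'
#' Histogram-based threshold maximizing the between-class variance; the
#' returned value is the upper edge of the selected bin.
#'
#' @param x non-negative intensities
#' @param nbins histogram resolution
#' @return scalar threshold
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  breaks[which.max(sigma_b) + 1L]
}

.check_cells <- function(cells) {
  need <- c("case_id", "compartment_region", "compartment_context",
            .mif_markers)
  missing <- setdiff(need, colnames(cells))
  if (length(missing))
    stop("cell table missing column(s): ", paste(missing, collapse = ", "))
  cells
}

#' Phenotype cells by marker thresholding
#'
#' Each cell receives one boolean per rule: positive when every marker in
#' the rule's conjunction is at or above its threshold. Thresholds are fixed
#' per marker (supplied) or computed per marker by Otsu's method on the
#' pooled intensities. A cell may satisfy several rules. The thresholds used
#' are recorded as an attribute.
#'
#' @param cells cell table (see \code{\link{simulateCellTables}} or
#'   \code{\link{readCellTable}})
#' @param rules list of \code{\link{phenotypeRule}}s
#' @param thresholds named per-marker thresholds (for
#'   \code{thresholdSource = "fixed"})
#' @param thresholdSource "fixed" or "otsu_per_marker"
#' @return the cell table with one logical column per rule (named by the
#'   rule) and attribute \code{thresholds}
#' @export
phenotypeCells <- function(cells, rules = defaultPhenotypeRules(),
                           thresholds = NULL,
                           thresholdSource = c("fixed", "otsu_per_marker")) {
  thresholdSource <- match.arg(thresholdSource)
  cells <- .check_cells(cells)
  used <- unique(unlist(lapply(rules, `[[`, "markers")))
  if (thresholdSource == "otsu_per_marker") {
    thresholds <- vapply(used, function(m) otsuThreshold(cells[[m]]),
                         numeric(1))
  } else {
    if (is.null(thresholds))
      stop("thresholdSource='fixed' needs named per-marker thresholds")
    missing <- setdiff(used, names(thresholds))
    if (length(missing))
      stop("no threshold for marker(s): ", paste(missing, collapse = ", "))
    if (any(thresholds <= 0)) stop("thresholds must be > 0")
  }
  for (r in rules) {
    pos <- rep(TRUE, nrow(cells))
    for (m in r$markers) pos <- pos & cells[[m]] >= thresholds[[m]]
    cells[[r$name]] <- pos
  }
  attr(cells, "thresholds") <- thresholds[used]
  attr(cells, "phenotypes") <- vapply(rules, `[[`, character(1), "name")
  cells
}

# map the region x context compartment onto the requested stratification
.strat_compartment <- function(cells, stratification) {
  region <- cells$compartment_region
  context <- cells$compartment_context
  switch(stratification,
    full = paste(region, context, sep = "_"),
    TLS_vs_stroma = ifelse(context == "stroma", "stroma", "TLS"),
    IM_vs_CT = ifelse(context == "stroma", NA_character_, region),
    GC_vs_noGC = ifelse(context == "stroma", NA_character_, context))
}

#' Per-compartment phenotype composition
#'
#' Percent of all cells in a compartment satisfying each phenotype
#' (HALO-style denominator: the compartment's total cell count), per case.
#' Stratifications: \code{"full"} keeps region x context compartments;
#' \code{"TLS_vs_stroma"} pools TLSs against stroma;
#' \code{"IM_vs_CT"} and \code{"GC_vs_noGC"} compare TLS cells only (stroma
#' cells are dropped). Pooling across compartments is count-weighted, never
#' an average of percentages.
#'
#' @param cells phenotyped cell table from \code{\link{phenotypeCells}}
#' @param stratification one of "full", "TLS_vs_stroma", "IM_vs_CT",
#'   "GC_vs_noGC"
#' @return data.frame: case_id, compartment, phenotype, n_cells, n_pos,
#'   percent
#' @export
compositionSummary <- function(cells,
                               stratification = c("full", "TLS_vs_stroma",
                                                  "IM_vs_CT",
                                                  "GC_vs_noGC")) {
  stratification <- match.arg(stratification)
  phen <- attr(cells, "phenotypes")
  if (is.null(phen))
    stop("cells must be phenotyped first (phenotypeCells)")
  comp <- .strat_compartment(cells, stratification)
  keep <- !is.na(comp)
  cells <- cells[keep, , drop = FALSE]
  comp <- comp[keep]
  key <- interaction(cells$case_id, comp, drop = TRUE, sep = "\r")
  n_cells <- as.vector(table(key))
  lv <- levels(key)
  parts <- do.call(rbind, strsplit(lv, "\r", fixed = TRUE))
  rows <- lapply(phen, function(ph) {
    n_pos <- vapply(split(cells[[ph]], key), sum, numeric(1))
    data.frame(case_id = parts[, 1], compartment = parts[, 2],
               phenotype = ph, n_cells = n_cells,
               n_pos = as.vector(n_pos),
               percent = 100 * as.vector(n_pos) / n_cells,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Correlation between percent-positive and mean positive intensity
#'
#' Per marker: Pearson correlation across cases between the percentage of
#' positive cells and the mean fluorescence intensity among the positive
#' cells.
#'
#' @param cells phenotyped cell table (needs the single-marker phenotype
#'   columns "\code{<marker>+}")
#' @param markers markers to evaluate
#' @return data.frame: marker, r, p, n_cases
#' @export
intensityPercentCorrelation <- function(cells, markers = mifPanel()) {
  if (is.null(attr(cells, "phenotypes")))
    stop("cells must be phenotyped first (phenotypeCells)")
  rows <- lapply(markers, function(m) {
    ph <- paste0(m, "+")
    if (!ph %in% colnames(cells))
      stop("missing phenotype column: ", ph)
    per_case <- split(seq_len(nrow(cells)), cells$case_id)
    if (length(per_case) < 3L) stop("need >= 3 cases")
    pct <- vapply(per_case, function(i) 100 * mean(cells[[ph]][i]),
                  numeric(1))
    mfi <- vapply(per_case, function(i) {
      pos <- i[cells[[ph]][i]]
      if (length(pos)) mean(cells[[m]][pos]) else NA_real_
    }, numeric(1))
    ok <- is.finite(pct) & is.finite(mfi)
    ct <- correlationTest(pct[ok], mfi[ok], method = "pearson")
    data.frame(marker = m, r = ct$r, p = ct$p.value, n_cases = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# dendrogram -> nested list of merge heights and leaf labels
.dend_to_list <- function(hc) {
  build <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    list(height = hc$height[i],
         children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
  }
  build(nrow(hc$merge))
}

#' Co-infiltration hierarchical clustering
#'
#' Agglomerative clustering of cases/compartments by their phenotype
#' frequency profiles (percent scale, unscaled by default; optional row
#' z-scoring). Defaults: Euclidean distance, average linkage.
#'
#' @param mat numeric matrix, rows = cases or compartments, cols =
#'   phenotype frequencies; no missing values
#' @param linkage hclust agglomeration method (default "average")
#' @param metric dist metric (default "euclidean")
#' @param scale z-score columns before clustering (recorded in the result)
#' @return list of class \code{coinfiltration_clust}: \code{hclust}, leaf
#'   \code{order} (labels), \code{json} (nested dendrogram with merge
#'   heights, serializable with jsonlite), \code{scaled}
#' @export
coinfiltrationCluster <- function(mat, linkage = "average",
                                  metric = "euclidean", scale = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 rows to cluster")
  bad <- rownames(mat)[!stats::complete.cases(mat)]
  if (length(bad))
    stop("rows with missing frequencies: ", paste(bad, collapse = ", "))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row_", seq_len(nrow(mat)))
  if (scale) mat <- base::scale(mat)
  hc <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
  structure(list(hclust = hc, order = hc$labels[hc$order],
                 json = .dend_to_list(hc), scaled = scale),
            class = "coinfiltration_clust")
}
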