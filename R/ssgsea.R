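# Single-sample gene-set enrichment scoring and survival-based
# dichotomization into signature-high / signature-low groups.

.as_expr_matrix <- function(cohort) {
  if (methods::is(cohort, "TLSCohort"))
    SummarizedExperiment::assay(cohort, "exprs")
  else as.matrix(cohort)
}

# positions of set genes after symbol normalization; errors when empty
.match_set <- function(set_genes, gene_norm, set_name) {
  idx <- which(gene_norm %in% normalizeGeneSymbols(set_genes))
  if (!length(idx)) {
    missing <- setdiff(normalizeGeneSymbols(set_genes), gene_norm)
    stop("gene set '", set_name, "' shares no genes with the cohort; ",
         "missing: ", paste(missing, collapse = ", "))
  }
  if (length(idx) == length(gene_norm))
    stop("gene set '", set_name,
         "' covers every cohort gene; no out-of-set genes remain")
  idx
}

#' Per-sample ssGSEA signature scores
#'
#' For each sample, genes are ranked by expression in decreasing order (ties
#' broken by gene symbol, lexicographically, for determinism) and assigned
#' the rank statistic N..1. Walking down the ranking, the running sum gains
#' \code{|rank|^alpha / sum(|rank|^alpha over the set)} at in-set genes and
#' loses \code{1 / (N - |S|)} at out-of-set genes; the score is the sum of
#' the running-sum values over all N positions. The score depends on the
#' expression values only through their per-sample ordering, so it is
#' invariant under any strictly increasing per-sample transform.
#'
#' @param cohort a \linkS4class{TLSCohort} or genes x samples matrix with
#'   gene symbols as rownames
#' @param sets named list of gene-symbol vectors (e.g.
#'   \code{\link{tlsSignatureSets}})
#' @param alpha rank-weighting exponent (default 0.25)
#' @param normalize min-max normalize each signature's scores across samples
#' @return long-format score table: \code{sample_id}, \code{signature},
#'   \code{score}, plus \code{label}, \code{cutoff}, \code{cutoff_method}
#'   columns (NA until \code{\link{dichotomize}} fills them)
#' @examples
#' m <- matrix(rnorm(600), 60, 10,
#'             dimnames = list(sprintf("G%02d", 1:60), paste0("S", 1:10)))
#' head(ssgseaScore(m, list(demo = c("G01", "G07", "G21"))))
#' @export
ssgseaScore <- function(cohort, sets, alpha = 0.25, normalize = FALSE) {
  X <- .as_expr_matrix(cohort)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a uniquely named list")
  gene_norm <- normalizeGeneSymbols(rownames(X))
  if (anyDuplicated(gene_norm))
    stop("duplicate gene symbols after normalization: ",
         paste(unique(gene_norm[duplicated(gene_norm)]), collapse = ", "))
  N <- nrow(X)
  set_idx <- lapply(seq_along(sets), function(k)
    .match_set(sets[[k]], gene_norm, names(sets)[k]))
  names(set_idx) <- names(sets)

  rankstat <- (N:1)^alpha
  scores <- matrix(NA_real_, ncol(X), length(sets),
                   dimnames = list(colnames(X), names(sets)))
  for (j in seq_len(ncol(X))) {
    ord <- order(-X[, j], gene_norm)   # descending expr, lexicographic ties
    pos_of_gene <- integer(N)
    pos_of_gene[ord] <- seq_len(N)
    for (k in seq_along(set_idx)) {
      in_pos <- sort(pos_of_gene[set_idx[[k]]])
      m <- length(in_pos)
      steps <- rep(-1 / (N - m), N)
      steps[in_pos] <- rankstat[in_pos] / sum(rankstat[in_pos])
      scores[j, k] <- sum(cumsum(steps))
    }
  }
  if (normalize) {
    rng <- apply(scores, 2, range)
    scores <- sweep(scores, 2, rng[1, ], "-")
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    scores <- sweep(scores, 2, span, "/")
  }
  out <- data.frame(
    sample_id = rep(rownames(scores), times = ncol(scores)),
    signature = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    label = NA_character_, cutoff = NA_real_, cutoff_method = NA_character_,
    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  out
}

#' Dichotomize a signature score into high (+) and low (-) groups
#'
#' Labels a signature's samples \code{"+"} when score > cutoff and
#' \code{"-"} otherwise. The cutoff comes from maximally selected rank
#' statistics against survival (\code{method = "maxstat"}, the default;
#' requires survival data), the median, or a fixed constant. The cutoff and
#' method are recorded on the labelled rows.
#'
#' @param scores score table from \code{\link{ssgseaScore}}
#' @param signature which signature to dichotomize
#' @param method "maxstat", "median" or "fixed"
#' @param survival data.frame with id, time_months, event (needed for
#'   maxstat); ids matched to \code{sample_id}
#' @param cutoff fixed cutoff when \code{method = "fixed"}
#' @param ... passed to \code{\link{maxstatCutpoint}} (minprop, pMethod,
#'   nPerm, seed)
#' @return the score table with label/cutoff/cutoff_method filled for the
#'   chosen signature
#' @export
dichotomize <- function(scores, signature,
                        method = c("maxstat", "median", "fixed"),
                        survival = NULL, cutoff = NULL, ...) {
  method <- match.arg(method)
  rows <- which(scores$signature == signature)
  if (!length(rows)) stop("signature '", signature, "' not in score table")
  x <- scores$score[rows]
  if (length(unique(x)) < 2L)
    stop("all scores identical for '", signature,
         "': no admissible cutoff")
  cut <- switch(method,
    median = median(x),
    fixed = {
      if (is.null(cutoff)) stop("method='fixed' needs a cutoff")
      cutoff
    },
    maxstat = {
      if (is.null(survival))
        stop("method='maxstat' needs survival data")
      idx <- match(scores$sample_id[rows], survival$id)
      if (anyNA(idx))
        stop("samples missing from survival data: ",
             paste(scores$sample_id[rows][is.na(idx)], collapse = ", "))
      maxstatCutpoint(x, survival$time_months[idx],
                      survival$event[idx], ...)$cutpoint
    })
  scores$label[rows] <- ifelse(x > cut, "+", "-")
  scores$cutoff[rows] <- cut
  scores$cutoff_method[rows] <- method
  scores
}
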