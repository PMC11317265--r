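# Two-class GSEA: signal-to-noise gene ranking, weighted Kolmogorov-Smirnov
# enrichment score, phenotype-permutation p-values, NES and NES-based FDR.

# signal-to-noise statistic per gene; sd floored at max(0.2|mean|, eps)
.signal_to_noise <- function(X, pos, eps = 1e-8) {
  Xp <- X[, pos, drop = FALSE]
  Xn <- X[, !pos, drop = FALSE]
  m1 <- rowMeans(Xp); m2 <- rowMeans(Xn)
  s1 <- apply(Xp, 1, sd); s2 <- apply(Xn, 1, sd)
  s1 <- pmax(s1, 0.2 * abs(m1), eps)
  s2 <- pmax(s2, 0.2 * abs(m2), eps)
  (m1 - m2) / (s1 + s2)
}

# weighted KS running-sum enrichment score (weight exponent 1);
# returns the signed extreme deviation and its position
.gsea_es <- function(stat_sorted, in_set_sorted) {
  N <- length(stat_sorted)
  m <- sum(in_set_sorted)
  w <- abs(stat_sorted) * in_set_sorted
  denom <- sum(w)
  if (denom == 0) w[in_set_sorted] <- 1 / m else w <- w / denom
  steps <- w - (!in_set_sorted) / (N - m)
  rs <- cumsum(steps)
  i <- which.max(abs(rs))
  list(es = rs[i], at = i, running = rs)
}

#' Two-class GSEA between signature-high and signature-low samples
#'
#' Genes are ranked by the signal-to-noise statistic
#' \code{(mu+ - mu-) / (sd+ + sd-)} (each sd floored at
#' \code{max(0.2 |mu|, 1e-8)}), descending, ties broken by gene symbol. Each
#' set's enrichment score (ES) is the extreme of the weighted
#' Kolmogorov-Smirnov running sum (weight exponent 1). Nominal p-values come
#' from phenotype permutations preserving class sizes; the normalized ES
#' (NES) divides ES by the mean |permuted ES| of the same sign, and FDR q is
#' the standard NES-based ratio estimate.
#'
#' @param cohort a \linkS4class{TLSCohort} or genes x samples matrix
#' @param labels per-sample class labels, "+" / "-" (character vector
#'   aligned with the samples); >= 3 samples per class
#' @param sets named list of gene-symbol vectors
#' @param nPerm number of phenotype permutations (warning when < 100)
#' @param seed RNG seed for the permutations
#' @return data.frame per set: name, size, ES, NES, p, q,
#'   leading_edge (comma-separated genes); attributes n_perm and seed
#' @export
gseaTwoClass <- function(cohort, labels, sets, nPerm = 1000L, seed = NULL) {
  X <- .as_expr_matrix(cohort)
  if (length(labels) != ncol(X))
    stop("labels must have one entry per sample")
  if (!all(labels %in% c("+", "-")))
    stop("labels must be '+' or '-'")
  pos <- labels == "+"
  if (sum(pos) < 3L || sum(!pos) < 3L)
    stop("each class needs >= 3 samples")
  if (nPerm < 100L) warning("nPerm < 100 gives unstable p-values")
  gene_norm <- normalizeGeneSymbols(rownames(X))
  set_members <- lapply(seq_along(sets), function(k) {
    idx <- .match_set(sets[[k]], gene_norm, names(sets)[k])
    gene_norm[idx]
  })
  names(set_members) <- names(sets)

  es_for_labels <- function(p) {
    s <- .signal_to_noise(X, p)
    ord <- order(-s, gene_norm)
    s_sorted <- s[ord]
    g_sorted <- gene_norm[ord]
    vapply(set_members, function(genes)
      .gsea_es(s_sorted, g_sorted %in% genes)$es, numeric(1))
  }

  # observed, with leading edge
  s_obs <- .signal_to_noise(X, pos)
  ord <- order(-s_obs, gene_norm)
  s_sorted <- s_obs[ord]; g_sorted <- gene_norm[ord]
  obs <- lapply(set_members, function(genes) {
    r <- .gsea_es(s_sorted, g_sorted %in% genes)
    inset <- which(g_sorted %in% genes)
    lead <- if (r$es >= 0) inset[inset <= r$at] else inset[inset >= r$at]
    list(es = r$es, lead = g_sorted[lead])
  })
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  perm_es <- .with_seed(seed, {
    vapply(seq_len(nPerm), function(b) {
      p <- logical(length(labels))
      p[sample(length(labels), sum(pos))] <- TRUE
      es_for_labels(p)
    }, numeric(length(sets)))
  })
  perm_es <- matrix(perm_es, nrow = length(sets))

  p_nom <- nes <- numeric(length(sets))
  nes_perm <- matrix(NA_real_, length(sets), nPerm)
  for (k in seq_along(sets)) {
    pe <- perm_es[k, ]
    same <- if (es_obs[k] >= 0) pe[pe >= 0] else pe[pe < 0]
    p_nom[k] <- if (length(same))
      mean(abs(same) >= abs(es_obs[k])) else 1
    mpos <- mean(pe[pe >= 0]); mneg <- mean(abs(pe[pe < 0]))
    nes[k] <- if (es_obs[k] >= 0) es_obs[k] / mpos else -abs(es_obs[k]) / mneg
    nes_perm[k, pe >= 0] <- pe[pe >= 0] / mpos
    nes_perm[k, pe < 0] <- -abs(pe[pe < 0]) / mneg
  }
  # NES-based FDR: fraction of permuted NES at least as extreme, over the
  # fraction of observed NES at least as extreme (capped at 1)
  q <- vapply(seq_along(sets), function(k) {
    if (is.na(nes[k])) return(NA_real_)
    if (nes[k] >= 0) {
      num <- mean(nes_perm[!is.na(nes_perm)] >= nes[k])
      den <- mean(nes[!is.na(nes)] >= nes[k])
    } else {
      num <- mean(nes_perm[!is.na(nes_perm)] <= nes[k])
      den <- mean(nes[!is.na(nes)] <= nes[k])
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(
    name = names(sets),
    size = vapply(set_members, length, integer(1)),
    ES = es_obs, NES = nes, p = p_nom, q = q,
    leading_edge = vapply(obs, function(o) paste(o$lead, collapse = ","),
                          character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- nPerm
  attr(out, "seed") <- seed
  out
}
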