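# Orchestration: one resolved configuration drives the three analysis arms
# (transcriptome, histology, mIF); every result bundle embeds the resolved
# config and seed for auditability.

#' Pipeline configuration
#'
#' All tunables in one document; every run embeds the resolved values in its
#' result bundle.
#'
#' @param seed master RNG seed for every stochastic stage
#' @param bandWidthMm IM half-width in mm (default 2.5)
#' @param ssgseaAlpha ssGSEA rank-weighting exponent (default 0.25)
#' @param maxstatMinprop minimum group fraction for cutpoint candidates
#' @param nPerm permutations for maxstat and GSEA p-values
#' @param coxTies Cox tie handling, "efron" or "breslow"
#' @param dichotomizeMethod default score dichotomization
#' @param thresholds named per-marker mIF intensity thresholds
#' @return list of class \code{tls_config}
#' @export
tlsConfig <- function(seed = 1L, bandWidthMm = 2.5, ssgseaAlpha = 0.25,
                      maxstatMinprop = 0.1, nPerm = 1000L,
                      coxTies = c("efron", "breslow"),
                      dichotomizeMethod = c("maxstat", "median"),
                      thresholds = c("CD20" = 3, "CD8" = 3, "FOXP3" = 3,
                                     "CD23" = 3, "DC-LAMP" = 3,
                                     "PD-1" = 3)) {
  structure(list(seed = as.integer(seed), bandWidthMm = bandWidthMm,
                 ssgseaAlpha = ssgseaAlpha,
                 maxstatMinprop = maxstatMinprop, nPerm = as.integer(nPerm),
                 coxTies = match.arg(coxTies),
                 dichotomizeMethod = match.arg(dichotomizeMethod),
                 thresholds = thresholds),
            class = "tls_config")
}

.km_by_group <- function(surv, labels) {
  lapply(split(seq_along(labels), labels), function(i)
    kmEstimate(surv$time_months[i], surv$event[i]))
}

.run_transcriptome <- function(config, inputs) {
  cohort <- inputs$cohort
  if (is.null(cohort)) stop("transcriptome arm needs inputs$cohort")
  sets <- if (!is.null(inputs$sets)) inputs$sets else tlsSignatureSets()
  surv <- survivalData(cohort)
  scores <- ssgseaScore(cohort, sets, alpha = config$ssgseaAlpha)
  for (sig in names(sets))
    scores <- dichotomize(scores, sig, method = config$dichotomizeMethod,
                          survival = surv,
                          minprop = config$maxstatMinprop,
                          pMethod = "none")
  lab <- function(sig) {
    sub <- scores[scores$signature == sig, ]
    setNames(sub$label, sub$sample_id)
  }
  labels <- lapply(setNames(names(sets), names(sets)), lab)
  ids <- surv$id

  nested <- list()
  grp <- labels[[1]][ids]
  nested[[paste0(names(sets)[1], "+/-")]] <- list(
    logrank = logrankTest(surv$time_months, surv$event, grp),
    km = .km_by_group(surv, grp))
  if (length(sets) >= 2) {
    keep <- grp == "+"
    g2 <- labels[[2]][ids][keep]
    if (length(unique(g2)) == 2L)
      nested[[paste0(names(sets)[1], "+ ", names(sets)[2], "+/-")]] <- list(
        logrank = logrankTest(surv$time_months[keep], surv$event[keep], g2),
        km = .km_by_group(surv[keep, ], g2))
    if (length(sets) >= 3) {
      keep3 <- keep & labels[[2]][ids] == "+"
      g3 <- labels[[3]][ids][keep3]
      if (length(unique(g3)) == 2L)
        nested[[paste0(names(sets)[1], "+", names(sets)[2], "+ ",
                       names(sets)[3], "+/-")]] <- list(
          logrank = logrankTest(surv$time_months[keep3],
                                surv$event[keep3], g3),
          km = .km_by_group(surv[keep3, ], g3))
    }
  }
  gsea <- NULL
  gl <- labels[[1]][colnames(cohort)]
  if (min(table(gl)) >= 3L)
    gsea <- gseaTwoClass(cohort, unname(gl), sets,
                         nPerm = config$nPerm, seed = config$seed)
  list(scores = scores, groups = labels, nested_survival = nested,
       gsea = gsea)
}

.run_histology <- function(config, inputs) {
  if (is.null(inputs$events) || is.null(inputs$survival))
    stop("histology arm needs inputs$events and inputs$survival")
  partition <- inputs$partition
  if (is.null(partition)) {
    if (is.null(inputs$boundary))
      stop("histology arm needs inputs$partition or inputs$boundary")
    partition <- buildZones(inputs$boundary, config$bandWidthMm,
                            tissueExtent = inputs$tissueExtent)
  }
  score_set <- computeTLSScores(inputs$events, partition)
  sc <- scoreTable(score_set)
  surv <- inputs$survival
  idx <- match(surv$id, sc$case_id)
  if (anyNA(idx))
    stop("cases without scores: ", paste(surv$id[is.na(idx)], collapse = ", "))
  x <- sc$IM_TLS_D_GC[idx]
  ms <- maxstatCutpoint(x, surv$time_months, surv$event,
                        minprop = config$maxstatMinprop,
                        pMethod = "permutation", nPerm = config$nPerm,
                        seed = config$seed)
  grp <- factor(ifelse(x > ms$cutpoint, "high", "low"),
                levels = c("low", "high"))
  dat <- data.frame(surv, im_tls_gc_group = grp,
                    stringsAsFactors = FALSE)
  covs <- "im_tls_gc_group"
  extra <- intersect(inputs$covariates,
                     colnames(dat))
  covs_multi <- unique(c(covs, extra))
  cox_uni <- coxFit(dat, covs_multi, mode = "univariate",
                    ties = config$coxTies)
  cox_multi <- if (length(covs_multi) > 1L)
    coxFit(dat, covs_multi, mode = "multivariate", ties = config$coxTies)
  else cox_uni
  assoc <- NULL
  if (!is.null(inputs$clinical)) {
    cl <- inputs$clinical
    cl$im_tls_gc_group <- grp[match(cl$id, surv$id)]
    assoc <- associationTable(cl[, setdiff(colnames(cl), "id"),
                                 drop = FALSE], "im_tls_gc_group")
  }
  list(partition = partition, scores = score_set, cutpoint = ms,
       group = setNames(as.character(grp), surv$id),
       logrank = logrankTest(surv$time_months, surv$event, grp),
       km = .km_by_group(surv, grp),
       cox_univariate = cox_uni, cox_multivariate = cox_multi,
       associations = assoc)
}

.run_mif <- function(config, inputs) {
  if (is.null(inputs$cells)) stop("mif arm needs inputs$cells")
  labelled <- phenotypeCells(inputs$cells, defaultPhenotypeRules(),
                             thresholds = config$thresholds)
  comp_full <- compositionSummary(labelled, "full")
  comp_tls <- compositionSummary(labelled, "TLS_vs_stroma")
  dc <- comp_full[comp_full$phenotype == "DC-LAMP+", ]
  dc_groups <- list(
    IM_TLS_GC = dc$percent[dc$compartment == "IM_TLS_GC"],
    CT_TLS_GC = dc$percent[dc$compartment == "CT_TLS_GC"],
    TLS_noGC = dc$percent[dc$compartment %in% c("IM_TLS_noGC",
                                                "CT_TLS_noGC")],
    stroma = dc$percent[dc$compartment %in% c("IM_stroma", "CT_stroma")])
  dc_anova <- groupCompare(unlist(dc_groups),
                           rep(names(dc_groups), lengths(dc_groups)),
                           method = "anova_oneway")
  co_phen <- c("PD1+CD20+", "FOXP3+CD8+", "PD1+CD8+", "PD1+FOXP3+")
  co <- comp_full[comp_full$phenotype %in% co_phen, ]
  mat <- do.call(rbind, lapply(split(co, paste(co$case_id, co$compartment,
                                               sep = "|")),
                               function(d) setNames(d$percent, d$phenotype)))
  clust <- coinfiltrationCluster(mat)
  list(cells = labelled, composition_full = comp_full,
       composition_tls_stroma = comp_tls, dc_lamp_anova = dc_anova,
       coinfiltration = clust,
       intensity_correlation = intensityPercentCorrelation(labelled))
}

#' Run the analysis pipeline
#'
#' Executes one or all of the three arms on the supplied inputs. Every
#' result bundle carries the resolved configuration and seed; identical
#' config and inputs reproduce the bundle exactly.
#'
#' @param config a \code{\link{tlsConfig}}
#' @param arm "transcriptome", "histology", "mif" or "all"
#' @param inputs named list; per arm:
#'   transcriptome: \code{cohort} (\linkS4class{TLSCohort}), optional
#'   \code{sets}; histology: \code{events}, \code{survival}, and
#'   \code{partition} or \code{boundary} (+ optional \code{tissueExtent},
#'   \code{clinical}, \code{covariates}); mif: \code{cells}.
#' @return list of class \code{tls_results} with one element per arm plus
#'   \code{config}
#' @export
runPipeline <- function(config = tlsConfig(),
                        arm = c("all", "transcriptome", "histology", "mif"),
                        inputs = list()) {
  arm <- match.arg(arm)
  stopifnot(inherits(config, "tls_config"))
  res <- list(config = unclass(config))
  run <- function(which) arm %in% c("all", which)
  if (run("transcriptome") && (!is.null(inputs$cohort) || arm != "all"))
    res$transcriptome <- .run_transcriptome(config, inputs)
  if (run("histology") && (!is.null(inputs$events) || arm != "all"))
    res$histology <- .run_histology(config, inputs)
  if (run("mif") && (!is.null(inputs$cells) || arm != "all"))
    res$mif <- .run_mif(config, inputs)
  structure(res, class = "tls_results")
}

#' Render result tables
#'
#' Writes human-readable TSVs from a result bundle: a Table-1-layout file
#' (univariate and multivariate Cox columns), a Table-2-layout association
#' file with star annotations, KM step functions, composition summaries,
#' and the resolved configuration as JSON. Regeneration from the same
#' bundle is byte-idempotent.
#'
#' @param results a \code{tls_results} bundle from \code{\link{runPipeline}}
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
renderReports <- function(results, dir) {
  stopifnot(inherits(results, "tls_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  jsonlite::write_json(results$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(dir, "config.json"))
  h <- results$histology
  if (!is.null(h)) {
    uni <- h$cox_univariate
    multi <- h$cox_multivariate
    t1 <- data.frame(
      term = uni$term,
      uni_HR = sprintf("%.2f(%.2f-%.2f)", uni$HR, uni$ci_low, uni$ci_high),
      uni_p = signif(uni$p, 3),
      multi_HR = sprintf("%.2f(%.2f-%.2f)",
                         multi$HR[match(uni$term, multi$term)],
                         multi$ci_low[match(uni$term, multi$term)],
                         multi$ci_high[match(uni$term, multi$term)]),
      multi_p = signif(multi$p[match(uni$term, multi$term)], 3),
      stringsAsFactors = FALSE)
    emit(t1, "table1_cox.tsv")
    if (!is.null(h$associations)) {
      a <- h$associations
      a$p <- signif(a$p, 4)
      emit(a, "table2_associations.tsv")
    }
    for (g in names(h$km))
      emit(h$km[[g]], sprintf("km_histology_%s.tsv", g))
    emit(scoreTable(h$scores), "tls_scores.tsv")
  }
  tr <- results$transcriptome
  if (!is.null(tr)) {
    emit(tr$scores, "signature_scores.tsv")
    if (!is.null(tr$gsea)) {
      emit(tr$gsea, "gsea.tsv")
    }
    lr <- do.call(rbind, lapply(names(tr$nested_survival), function(nm) {
      x <- tr$nested_survival[[nm]]$logrank
      data.frame(comparison = nm, chi2 = x$chi2, df = x$df,
                 p = x$p.value, stars = pStars(x$p.value))
    }))
    emit(lr, "logrank_nested.tsv")
  }
  if (!is.null(results$mif)) {
    emit(results$mif$composition_full, "mif_composition.tsv")
    jsonlite::write_json(results$mif$coinfiltration$json,
                         file.path(dir, "coinfiltration_dendrogram.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(dir, "coinfiltration_dendrogram.json"))
  }
  invisible(paths)
}
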