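# Synthetic-data module: expression cohorts driven by a latent TLS abundance,
# tissue geometries with Poisson TLS events and density-linked survival, and
# per-cell mIF marker tables with planted positivity.

#' Built-in gene signatures
#'
#' The 12-chemokine TLS signature (CCL2/3/4/5/8/18/19/21, CXCL9/10/11/13),
#' the germinal-centre signature quoted with surface-marker names (CD21,
#' CD23, CXCL13; normalized to CR2, FCER2, CXCL13), and a
#' \emph{non-authoritative placeholder} activated-dendritic-cell signature
#' (LAMP3, CD83, CCR7, CD80, CD86, CD40). The exact published DC and
#' immune-cell lists are not redistributed here; replace the DC slot with
#' your own list for real analyses.
#'
#' @return named list of character vectors of normalized gene symbols
#' @examples tlsSignatureSets()$GC
#' @export
tlsSignatureSets <- function() {
  lapply(list(
    TLS = c("CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18", "CCL19",
            "CCL21", "CXCL9", "CXCL10", "CXCL11", "CXCL13"),
    GC = c("CD21", "CD23", "CXCL13"),
    DC = c("LAMP3", "CD83", "CCR7", "CD80", "CD86", "CD40")
  ), normalizeGeneSymbols)
}

#' Configuration for the expression-cohort simulator
#'
#' The generative model: each sample carries a latent TLS abundance
#' \code{L ~ Normal(0, 1)}. Signature-gene expression is
#' \code{baseline + latentEffect * L + noise}; non-signature genes are
#' \code{baseline + noise} with \code{noise ~ Normal(0, noiseSd)}. Survival
#' is exponential with hazard
#' \code{baselineHazard * exp(logHazardBeta * L)}, administratively censored
#' at \code{censorTime} months. The default \code{logHazardBeta < 0} makes
#' high TLS abundance protective.
#'
#' @param nSamples number of samples (default 300, a GEO-scale cohort)
#' @param nGenes total genes including the signature genes (default 2000)
#' @param signatures named list of gene vectors; overlaps between lists are
#'   allowed and recorded
#' @param latentEffect expression shift per unit latent abundance (default 1)
#' @param noiseSd residual expression SD (> 0; default 1)
#' @param logHazardBeta log-hazard per unit latent abundance (default -0.5)
#' @param baselineHazard events per month at L = 0 (default 0.02)
#' @param censorTime administrative censoring time in months (default 60)
#' @param seed integer RNG seed
#' @return list of class \code{cohort_sim_config}
#' @export
cohortSimConfig <- function(nSamples = 300L, nGenes = 2000L,
                            signatures = tlsSignatureSets(),
                            latentEffect = 1, noiseSd = 1,
                            logHazardBeta = -0.5, baselineHazard = 0.02,
                            censorTime = 60, seed = 1L) {
  if (nSamples < 2L) stop("nSamples must be >= 2")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (baselineHazard <= 0 || censorTime <= 0)
    stop("baselineHazard and censorTime must be > 0")
  signatures <- lapply(signatures, normalizeGeneSymbols)
  all_genes <- unique(unlist(signatures))
  if (length(all_genes) > nGenes)
    stop("signature genes (", length(all_genes), ") exceed nGenes (",
         nGenes, ")")
  overlap <- if (length(signatures) > 1) {
    pairs <- utils::combn(names(signatures), 2, simplify = FALSE)
    Filter(length, lapply(setNames(pairs, vapply(pairs, paste,
                                                 character(1),
                                                 collapse = ":")),
                          function(p) intersect(signatures[[p[1]]],
                                                signatures[[p[2]]])))
  } else list()
  structure(list(nSamples = as.integer(nSamples),
                 nGenes = as.integer(nGenes),
                 signatures = signatures, latentEffect = latentEffect,
                 noiseSd = noiseSd, logHazardBeta = logHazardBeta,
                 baselineHazard = baselineHazard, censorTime = censorTime,
                 overlap = overlap, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate an expression cohort
#'
#' Draws a cohort from the model described in
#' \code{\link{cohortSimConfig}}. The latent abundance is stored only as
#' hidden truth (\code{\link{latentTruth}}), never in the analysis-facing
#' expression or survival data. Identical configs (including seed) give
#' bit-identical cohorts.
#'
#' @param config a \code{\link{cohortSimConfig}}
#' @return a \linkS4class{TLSCohort}
#' @examples
#' cohort <- simulateExpressionCohort(cohortSimConfig(nSamples = 20,
#'                                                    nGenes = 100))
#' @export
simulateExpressionCohort <- function(config = cohortSimConfig()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  .with_seed(config$seed, {
    sig_genes <- unique(unlist(config$signatures))
    n_fill <- config$nGenes - length(sig_genes)
    genes <- c(sig_genes, sprintf("FILLER%04d", seq_len(n_fill)))
    samples <- sprintf("S%03d", seq_len(config$nSamples))

    L <- rnorm(config$nSamples)
    baseline <- rnorm(config$nGenes, mean = 6, sd = 0.5)
    noise <- matrix(rnorm(config$nGenes * config$nSamples,
                          sd = config$noiseSd),
                    config$nGenes, config$nSamples)
    expr <- baseline + noise
    in_sig <- genes %in% sig_genes
    expr[in_sig, ] <- expr[in_sig, ] +
      config$latentEffect * matrix(L, sum(in_sig), config$nSamples,
                                   byrow = TRUE)
    dimnames(expr) <- list(genes, samples)

    hazard <- config$baselineHazard * exp(config$logHazardBeta * L)
    t_event <- rexp(config$nSamples, rate = hazard)
    time <- pmin(t_event, config$censorTime)
    event <- as.integer(t_event <= config$censorTime)
    surv <- data.frame(id = samples, time_months = time, event = event,
                       stringsAsFactors = FALSE)
    TLSCohort(expr, survival = surv,
              truth = list(latent = setNames(L, samples),
                           config = unclass(config)))
  })
}

#' Configuration for the tissue-geometry simulator
#'
#' The tumour boundary is a star-shaped closed curve
#' \code{R(theta) = R0 * (1 + sum_k a_k cos(k theta + phi_k))} sampled at
#' \code{nVertices} vertices. TLS events arise from independent homogeneous
#' Poisson processes in the CT and IM zones with intensities \code{lambdaCT}
#' and \code{lambdaIM} (events per mm^2); each event's maturation stage is
#' multinomial with zone-specific probabilities over (E, PFL, SFL). Survival
#' is exponential with hazard
#' \code{baselineHazard * exp(betaIMGC * d)} where \code{d} is the case's
#' IM-SFL density (SFL count in IM / IM area, per mm^2).
#'
#' @param nCases number of cases
#' @param meanRadius mean boundary radius R0 in mm
#' @param boundaryHarmonics list of numeric triples
#'   \code{c(amplitude, frequency, phase)}
#' @param bandWidth IM half-width, mm (default 2.5)
#' @param lambdaCT,lambdaIM TLS intensities per mm^2
#' @param maturationProbs list with elements \code{CT} and \code{IM}, each a
#'   probability vector over \code{c(E, PFL, SFL)} summing to 1
#' @param betaIMGC log-hazard per unit IM-SFL density (mm^2); the default
#'   -33 makes the median-split density contrast of the default geometry
#'   correspond to a hazard ratio near 0.4
#' @param baselineHazard hazard (events per month) at zero IM-SFL density;
#'   the default 0.27 puts the hazard at the default geometry's typical
#'   density (about 0.0875 per mm^2) near 0.015 per month, a realistic
#'   cohort event rate
#' @param censorTime,seed as in \code{\link{cohortSimConfig}}
#' @param nVertices boundary sampling density (>= 128)
#' @return list of class \code{tissue_sim_config}
#' @export
tissueSimConfig <- function(nCases = 166L, meanRadius = 10,
                            boundaryHarmonics = list(c(0.12, 3, 0.7),
                                                     c(0.06, 5, 2.1)),
                            bandWidth = 2.5, lambdaCT = 0.08,
                            lambdaIM = 0.25,
                            maturationProbs = list(
                              CT = c(E = 0.50, PFL = 0.30, SFL = 0.20),
                              IM = c(E = 0.35, PFL = 0.30, SFL = 0.35)),
                            betaIMGC = -33, baselineHazard = 0.27,
                            censorTime = 60, nVertices = 256L, seed = 1L) {
  if (lambdaCT < 0 || lambdaIM < 0) stop("lambda intensities must be >= 0")
  if (bandWidth <= 0) stop("bandWidth must be > 0")
  for (z in c("CT", "IM")) {
    p <- maturationProbs[[z]]
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("maturationProbs$", z, " must be 3 non-negative values summing to 1")
  }
  # a radial curve R(theta) > 0 is automatically simple; negative radii mean
  # the harmonics fold the boundary onto itself
  if (length(boundaryHarmonics)) {
    amp <- vapply(boundaryHarmonics, `[`, numeric(1), 1)
    if (sum(abs(amp)) >= 1) {
      worst <- which.max(abs(amp))
      stop("boundary radius reaches zero: harmonic ", worst,
           " (amplitude ", amp[worst], ") makes the boundary self-intersect")
    }
  }
  structure(list(nCases = as.integer(nCases), meanRadius = meanRadius,
                 boundaryHarmonics = boundaryHarmonics,
                 bandWidth = bandWidth, lambdaCT = lambdaCT,
                 lambdaIM = lambdaIM, maturationProbs = maturationProbs,
                 betaIMGC = betaIMGC, baselineHazard = baselineHazard,
                 censorTime = censorTime, nVertices = as.integer(nVertices),
                 seed = as.integer(seed)),
            class = "tissue_sim_config")
}

#' Tumour boundary polygon of a tissue configuration
#' @param config a \code{\link{tissueSimConfig}}
#' @return nVertices x 2 matrix (mm), counter-clockwise
#' @export
tumorBoundary <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  th <- seq(0, 2 * pi, length.out = config$nVertices + 1L)[-(config$nVertices + 1L)]
  r <- rep(config$meanRadius, length(th))
  for (h in config$boundaryHarmonics)
    r <- r + config$meanRadius * h[1] * cos(h[2] * th + h[3])
  cbind(x = r * cos(th), y = r * sin(th))
}

# rejection-sample n uniform points within one zone of the partition
.sample_zone_points <- function(n, zone, partition) {
  if (n == 0L)
    return(data.frame(x_mm = numeric(), y_mm = numeric()))
  b <- partition@boundary
  pad <- if (zone == "IM") partition@bandWidth else 0
  xr <- range(b[, 1]) + c(-1, 1) * pad
  yr <- range(b[, 2]) + c(-1, 1) * pad
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * n, 64L)
    cx <- runif(m, xr[1], xr[2]); cy <- runif(m, yr[1], yr[2])
    keep <- assignZone(cx, cy, partition) == zone
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  data.frame(x_mm = xs[seq_len(n)], y_mm = ys[seq_len(n)])
}

#' Simulate one tissue case
#'
#' Draws the TLS event set and survival record for a single case under the
#' model of \code{\link{tissueSimConfig}}. The per-case RNG stream is seeded
#' with \code{config$seed + caseIndex}, so a case is reproducible on its own
#' and within \code{\link{simulateTissueCohort}}.
#'
#' @param config a \code{\link{tissueSimConfig}}
#' @param caseIndex positive integer
#' @param partition optional precomputed \linkS4class{ZonePartition} for the
#'   configuration's boundary (built once by the cohort wrapper)
#' @return list with \code{events} (case_id, x_mm, y_mm, maturation, zone),
#'   \code{survival} (one-row data.frame), \code{im_sfl_density} and
#'   \code{partition}
#' @export
simulateTissueCase <- function(config, caseIndex = 1L, partition = NULL) {
  stopifnot(inherits(config, "tissue_sim_config"))
  if (is.null(partition))
    partition <- buildZones(tumorBoundary(config), config$bandWidth)
  .with_seed(config$seed + as.integer(caseIndex), {
    ev <- lapply(c("CT", "IM"), function(z) {
      lam <- if (z == "CT") config$lambdaCT else config$lambdaIM
      area <- if (z == "CT") partition@areaCT else partition@areaIM
      n <- rpois(1L, lam * area)
      pts <- .sample_zone_points(n, z, partition)
      if (n > 0L) {
        stage <- .maturation_levels[
          apply(rmultinom(n, 1L, config$maturationProbs[[z]]), 2L,
                which.max)]
      } else stage <- character()
      if (n > 0L) data.frame(pts, maturation = stage, zone = z,
                             stringsAsFactors = FALSE) else NULL
    })
    ev <- do.call(rbind, ev)
    if (is.null(ev))
      ev <- data.frame(x_mm = numeric(), y_mm = numeric(),
                       maturation = character(), zone = character(),
                       stringsAsFactors = FALSE)
    cid <- sprintf("case_%03d", as.integer(caseIndex))
    ev <- cbind(case_id = rep(cid, nrow(ev)), ev)
    d_im_sfl <- sum(ev$zone == "IM" & ev$maturation == "SFL-TLS") /
      partition@areaIM
    hazard <- config$baselineHazard * exp(config$betaIMGC * d_im_sfl)
    t_event <- rexp(1L, rate = hazard)
    surv <- data.frame(id = cid,
                       time_months = min(t_event, config$censorTime),
                       event = as.integer(t_event <= config$censorTime),
                       stringsAsFactors = FALSE)
    list(events = ev, survival = surv, im_sfl_density = d_im_sfl,
         partition = partition)
  })
}

#' Simulate a tissue cohort
#'
#' All cases share the configured boundary geometry (the zone partition is
#' built once); events and survival vary by case.
#'
#' @param config a \code{\link{tissueSimConfig}}
#' @param gridN area-quadrature resolution passed to \code{\link{buildZones}}
#' @return list with \code{partition}, \code{events} (all cases),
#'   \code{survival} (one row per case), and \code{truth} (per-case IM-SFL
#'   density)
#' @export
simulateTissueCohort <- function(config = tissueSimConfig(), gridN = 720L) {
  stopifnot(inherits(config, "tissue_sim_config"))
  partition <- buildZones(tumorBoundary(config), config$bandWidth,
                          gridN = gridN)
  cases <- lapply(seq_len(config$nCases), function(i)
    simulateTissueCase(config, i, partition))
  list(partition = partition,
       events = do.call(rbind, lapply(cases, `[[`, "events")),
       survival = do.call(rbind, lapply(cases, `[[`, "survival")),
       truth = list(im_sfl_density = vapply(cases, `[[`, numeric(1),
                                            "im_sfl_density")),
       config = config)
}

.mif_markers <- c("CD20", "CD8", "FOXP3", "CD23", "DC-LAMP", "PD-1")
.mif_compartments <- c("CT_TLS_GC", "CT_TLS_noGC", "CT_stroma",
                       "IM_TLS_GC", "IM_TLS_noGC", "IM_stroma")

.default_positivity <- function() {
  m <- rbind(
    CT_TLS_GC   = c(0.50, 0.25, 0.08, 0.25, 0.120, 0.35),
    CT_TLS_noGC = c(0.30, 0.25, 0.09, 0.04, 0.050, 0.18),
    CT_stroma   = c(0.05, 0.08, 0.02, 0.01, 0.015, 0.04),
    IM_TLS_GC   = c(0.42, 0.20, 0.05, 0.25, 0.200, 0.30),
    IM_TLS_noGC = c(0.28, 0.30, 0.12, 0.04, 0.050, 0.18),
    IM_stroma   = c(0.05, 0.08, 0.02, 0.01, 0.015, 0.04))
  colnames(m) <- .mif_markers
  m
}

#' Configuration for the mIF cell-table simulator
#'
#' Each compartment (region x context: CT/IM crossed with TLS-with-GC,
#' TLS-without-GC, stroma) receives a Poisson number of cells per case. Each
#' cell draws, per marker, a Bernoulli positivity with the compartment's
#' configured probability and an intensity from a log-normal (positive or
#' negative component). The default positivity matrix encodes the
#' directional structure reported for TLS biology: every marker enriched in
#' TLSs over stroma; DC-LAMP ordered IM-TLS-GC > CT-TLS-GC > TLS-noGC >
#' stroma; PD-1 and CD20 jointly higher (and FOXP3 with CD8 jointly lower)
#' in GC-positive IM-TLSs. Default intensity components are well separated
#' (idealized unmixing), so threshold phenotyping recovers the planted
#' labels almost surely.
#'
#' @param nCases number of tumours (default 12)
#' @param cellCounts named vector of Poisson means per compartment
#' @param positivityProbs compartment x marker probability matrix
#' @param intensityPos,intensityNeg \code{c(meanlog, sdlog)} of the positive
#'   and negative log-normal intensity components
#' @param seed RNG seed
#' @return list of class \code{cell_sim_config}
#' @export
cellSimConfig <- function(nCases = 12L,
                          cellCounts = c(CT_TLS_GC = 400, CT_TLS_noGC = 400,
                                         CT_stroma = 800, IM_TLS_GC = 400,
                                         IM_TLS_noGC = 400, IM_stroma = 800),
                          positivityProbs = .default_positivity(),
                          intensityPos = c(meanlog = 2.3, sdlog = 0.3),
                          intensityNeg = c(meanlog = 0.0, sdlog = 0.3),
                          seed = 1L) {
  if (!all(names(cellCounts) %in% .mif_compartments))
    stop("unknown compartment(s): ",
         paste(setdiff(names(cellCounts), .mif_compartments), collapse = ", "))
  if (!all(colnames(positivityProbs) %in% .mif_markers))
    stop("unknown marker(s): ",
         paste(setdiff(colnames(positivityProbs), .mif_markers),
               collapse = ", "))
  if (any(positivityProbs < 0 | positivityProbs > 1))
    stop("positivity probabilities must lie in [0, 1]")
  structure(list(nCases = as.integer(nCases), cellCounts = cellCounts,
                 positivityProbs = positivityProbs,
                 intensityPos = intensityPos, intensityNeg = intensityNeg,
                 seed = as.integer(seed)),
            class = "cell_sim_config")
}

#' Simulate mIF cell tables
#'
#' @param config a \code{\link{cellSimConfig}}
#' @return list with \code{cells} (case_id, x_mm, y_mm, compartment_region,
#'   compartment_context, one intensity column per marker) and \code{truth}
#'   (the planted per-cell positivity, same row order)
#' @examples
#' sim <- simulateCellTables(cellSimConfig(nCases = 2,
#'   cellCounts = c(CT_TLS_GC = 50, IM_stroma = 50)))
#' @export
simulateCellTables <- function(config = cellSimConfig()) {
  stopifnot(inherits(config, "cell_sim_config"))
  markers <- colnames(config$positivityProbs)
  .with_seed(config$seed, {
    blocks <- list(); truths <- list()
    for (ci in seq_len(config$nCases)) {
      cid <- sprintf("tumour_%02d", ci)
      for (comp in names(config$cellCounts)) {
        n <- rpois(1L, config$cellCounts[[comp]])
        if (n == 0L) next
        parts <- strsplit(comp, "_", fixed = TRUE)[[1]]
        region <- parts[1]
        context <- paste(parts[-1], collapse = "_")
        pos <- vapply(markers, function(mk)
          as.logical(rbinom(n, 1L, config$positivityProbs[comp, mk])),
          logical(n))
        pos <- matrix(pos, nrow = n,
                      dimnames = list(NULL, markers))
        inten <- vapply(markers, function(mk) {
          out <- rlnorm(n, config$intensityNeg[1], config$intensityNeg[2])
          k <- sum(pos[, mk])
          if (k) out[pos[, mk]] <- rlnorm(k, config$intensityPos[1],
                                          config$intensityPos[2])
          out
        }, numeric(n))
        inten <- matrix(inten, nrow = n, dimnames = list(NULL, markers))
        df <- data.frame(case_id = cid, x_mm = runif(n), y_mm = runif(n),
                         compartment_region = region,
                         compartment_context = context,
                         stringsAsFactors = FALSE, check.names = FALSE)
        df <- cbind(df, as.data.frame(inten, check.names = FALSE))
        blocks[[length(blocks) + 1L]] <- df
        truths[[length(truths) + 1L]] <-
          as.data.frame(pos, check.names = FALSE)
      }
    }
    list(cells = do.call(rbind, blocks), truth = do.call(rbind, truths),
         config = config)
  })
}

#' Simulate a two-group survival cohort with a planted hazard ratio
#'
#' Generates a cohort split into high/low IM-SFL-density groups with an
#' exact planted hazard ratio for the high group: exponential event times
#' with hazard \code{baselineHazard} (low) or \code{baselineHazard * hr}
#' (high), administratively censored. This is the instrument for
#' Cox-coverage checks, where the effect must be planted on the dichotomized
#' group itself.
#'
#' @param n cohort size (default 300)
#' @param hr planted hazard ratio of the high-density group (default 0.4)
#' @param pHigh probability of the high-density group (default 0.735, the
#'   observed high/low split of the motivating cohort)
#' @param baselineHazard events per month in the low group (default 0.015)
#' @param censorTime administrative censoring, months (default 60)
#' @param seed RNG seed (NULL = use current RNG state)
#' @return data.frame with id, group ("high"/"low"), time_months, event
#' @export
simulateSurvivalCohort <- function(n = 300L, hr = 0.4, pHigh = 0.735,
                                   baselineHazard = 0.015, censorTime = 60,
                                   seed = NULL) {
  stopifnot(n >= 2L, hr > 0, baselineHazard > 0, censorTime > 0)
  .with_seed(seed, {
    high <- rbinom(n, 1L, pHigh)
    hazard <- baselineHazard * ifelse(high == 1L, hr, 1)
    t_event <- rexp(n, rate = hazard)
    data.frame(id = sprintf("P%04d", seq_len(n)),
               group = ifelse(high == 1L, "high", "low"),
               time_months = pmin(t_event, censorTime),
               event = as.integer(t_event <= censorTime),
               stringsAsFactors = FALSE)
  })
}
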