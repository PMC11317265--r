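#' Expression cohort with survival metadata
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples expression matrix (assay \code{"exprs"}, assumed log-scale or
#' otherwise monotone in abundance) together with per-sample survival columns
#' \code{time_months} and \code{event} in \code{colData}. Simulated cohorts
#' additionally carry hidden ground truth (the latent TLS abundance) in
#' \code{metadata(x)$truth}; the truth never appears in the analysis-facing
#' on-disk exports, only in the sidecar written by
#' \code{\link{writeCohort}}.
#'
#' @aliases TLSCohort-class
#' @exportClass TLSCohort
setClass("TLSCohort", contains = "SummarizedExperiment")

setValidity("TLSCohort", function(object) {
  msg <- character()
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene symbols in rownames")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids in colnames")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- SummarizedExperiment::colData(object)
  if ("time_months" %in% colnames(cd)) {
    tm <- cd$time_months
    if (any(!is.na(tm) & tm <= 0))
      msg <- c(msg, "time_months must be > 0")
    if (!"event" %in% colnames(cd))
      msg <- c(msg, "time_months present without event column")
    else if (!all(cd$event %in% c(0L, 1L, NA)))
      msg <- c(msg, "event must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TLSCohort
#'
#' @param exprs numeric matrix, genes x samples, with unique rownames (gene
#'   symbols) and colnames (sample ids).
#' @param survival optional data.frame with columns \code{id},
#'   \code{time_months} (> 0) and \code{event} (0/1); matched to samples by
#'   \code{id}.
#' @param truth optional list of hidden simulation truth (e.g. the latent
#'   abundance), stored in \code{metadata}.
#' @return A \linkS4class{TLSCohort}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' TLSCohort(m)
#' @export
TLSCohort <- function(exprs, survival = NULL, truth = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("exprs must have gene symbols as rownames and sample ids as colnames")
  cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
  if (!is.null(survival)) {
    need <- c("id", "time_months", "event")
    if (!all(need %in% colnames(survival)))
      stop("survival needs columns: ", paste(need, collapse = ", "))
    idx <- match(colnames(exprs), survival$id)
    if (anyNA(idx))
      stop("samples without survival rows: ",
           paste(colnames(exprs)[is.na(idx)], collapse = ", "))
    cd$time_months <- survival$time_months[idx]
    cd$event <- as.integer(survival$event[idx])
    extra <- setdiff(colnames(survival), need)
    for (v in extra) cd[[v]] <- survival[[v]][idx]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  obj <- methods::new("TLSCohort", se)
  if (!is.null(truth)) S4Vectors::metadata(obj)$truth <- truth
  methods::validObject(obj)
  obj
}

#' Survival metadata of a cohort
#' @param x a \linkS4class{TLSCohort}
#' @return data.frame with id, time_months, event (plus any extra clinical
#'   columns), or NULL when the cohort carries no survival data.
#' @export
survivalData <- function(x) {
  stopifnot(methods::is(x, "TLSCohort"))
  cd <- SummarizedExperiment::colData(x)
  if (!"time_months" %in% colnames(cd)) return(NULL)
  out <- as.data.frame(cd)
  out <- cbind(id = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hidden simulation truth of a cohort
#' @param x a \linkS4class{TLSCohort}
#' @return the \code{truth} list stored at simulation time, or NULL.
#' @export
latentTruth <- function(x) {
  stopifnot(methods::is(x, "TLSCohort"))
  S4Vectors::metadata(x)$truth
}

#' Tumour-centre / invasive-margin partition of a tumour section
#'
#' Produced by \code{\link{buildZones}}. The tumour centre (CT) is the set of
#' points inside the tumour boundary farther than \code{bandWidth} from it;
#' the invasive margin (IM) is the band within \code{bandWidth} of the
#' boundary on either side, clipped to the tissue extent when one is given.
#' Areas are in mm^2; coordinates in mm.
#'
#' @slot boundary numeric matrix (n x 2) of boundary vertices, mm,
#'   counter-clockwise, simple (non-self-intersecting).
#' @slot tissueExtent numeric matrix (n x 2) or NULL; polygon containing the
#'   boundary that limits the outward reach of the IM.
#' @slot bandWidth half-width of the IM band in mm (2.5 by default upstream).
#' @slot areaCT,areaIM zone areas in mm^2.
#' @slot gridSpacing spacing (mm) of the deterministic grid used for the
#'   area quadrature.
#' @slot metadata list; carries flags such as \code{ct_empty} and
#'   \code{tissue_extent_assumed}.
#' @aliases ZonePartition-class
#' @exportClass ZonePartition
setClass("ZonePartition",
  representation(boundary = "matrix", tissueExtent = "ANY",
                 bandWidth = "numeric", areaCT = "numeric",
                 areaIM = "numeric", gridSpacing = "numeric",
                 metadata = "list"))

setValidity("ZonePartition", function(object) {
  msg <- character()
  if (ncol(object@boundary) != 2L || nrow(object@boundary) < 3L)
    msg <- c(msg, "boundary must be an n x 2 matrix with n >= 3")
  if (object@bandWidth <= 0) msg <- c(msg, "bandWidth must be > 0")
  if (object@areaCT < 0 || object@areaIM < 0)
    msg <- c(msg, "areas must be non-negative")
  if (object@areaIM == 0) msg <- c(msg, "areaIM must be > 0 for a non-degenerate boundary")
  if (length(msg)) msg else TRUE
})

#' @describeIn ZonePartition-class CT area in mm^2
#' @param x,object a \code{ZonePartition}
#' @export
areaCT <- function(x) { stopifnot(methods::is(x, "ZonePartition")); x@areaCT }

#' @describeIn ZonePartition-class IM area in mm^2
#' @export
areaIM <- function(x) { stopifnot(methods::is(x, "ZonePartition")); x@areaIM }

#' @describeIn ZonePartition-class IM half-width in mm
#' @export
bandWidth <- function(x) { stopifnot(methods::is(x, "ZonePartition")); x@bandWidth }

#' @describeIn ZonePartition-class boundary polygon vertex matrix (mm)
#' @export
boundaryPolygon <- function(x) { stopifnot(methods::is(x, "ZonePartition")); x@boundary }

setMethod("show", "ZonePartition", function(object) {
  cat("ZonePartition:", nrow(object@boundary), "boundary vertices,",
      "band", object@bandWidth, "mm\n")
  cat(sprintf("  area CT: %.3f mm^2  area IM: %.3f mm^2\n",
              object@areaCT, object@areaIM))
  if (isTRUE(object@metadata$ct_empty)) cat("  note: CT region is empty\n")
  if (isTRUE(object@metadata$tissue_extent_assumed))
    cat("  note: no tissue extent given; IM extends the full band outward\n")
  invisible(NULL)
})

#' Per-case TLS score set
#'
#' One row per case with the six TLS scores (counts and densities for CT, IM
#' and their union) computed over all events, plus the germinal-centre
#' restricted variants computed over secondary follicle-like (SFL) events
#' only. Densities are counts per mm^2; a density over a zero-area zone is
#' reported as NA (missing), never 0.
#'
#' @slot scores data.frame with columns \code{case_id},
#'   \code{CT_TLS_N, IM_TLS_N, Total_TLS_N, CT_TLS_D, IM_TLS_D, Total_TLS_D}
#'   and the same six suffixed \code{_GC}.
#' @slot bandWidth band width (mm) of the partition used.
#' @slot excluded integer count of events outside both zones, dropped before
#'   scoring.
#' @aliases TLSScoreSet-class
#' @exportClass TLSScoreSet
setClass("TLSScoreSet",
  representation(scores = "data.frame", bandWidth = "numeric",
                 excluded = "integer"))

setValidity("TLSScoreSet", function(object) {
  sc <- object@scores
  need <- c("case_id", "CT_TLS_N", "IM_TLS_N", "Total_TLS_N",
            "CT_TLS_D", "IM_TLS_D", "Total_TLS_D")
  if (!all(need %in% colnames(sc)))
    return(paste("missing score columns:",
                 paste(setdiff(need, colnames(sc)), collapse = ", ")))
  if (nrow(sc) &&
      !isTRUE(all.equal(sc$Total_TLS_N, sc$CT_TLS_N + sc$IM_TLS_N)))
    return("Total_TLS_N must equal CT_TLS_N + IM_TLS_N")
  TRUE
})

#' @describeIn TLSScoreSet-class the per-case score table
#' @param x,object a \code{TLSScoreSet}
#' @export
scoreTable <- function(x) { stopifnot(methods::is(x, "TLSScoreSet")); x@scores }

setMethod("show", "TLSScoreSet", function(object) {
  cat("TLSScoreSet:", nrow(object@scores), "case(s), band",
      object@bandWidth, "mm,", object@excluded,
      "event(s) outside both zones excluded\n")
  print(utils::head(object@scores, 5))
  invisible(NULL)
})
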