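# Readers and writers for the pipeline's plain-text interchange formats:
# GMT gene sets, TSV/GCT expression, clinical / event / cell CSVs, region
# GeoJSON, and score tables. Readers validate eagerly and report the
# offending line or row.

#' Read gene sets from a GMT file
#'
#' Standard tab-separated format: set name, description, then one gene per
#' field. Symbols are normalized (\code{\link{normalizeGeneSymbols}}).
#'
#' @param path GMT file
#' @return named list of gene vectors; descriptions kept as attribute
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": need name, description and >= 1 gene")
    genes <- normalizeGeneSymbols(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, ": empty gene list")
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene vectors
#' @param path output file
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read a genes x samples expression matrix
#'
#' Accepts plain TSV (first column gene symbols, remaining columns samples)
#' or GCT (version line \code{#1.2}, dimension line, then Name /
#' Description / sample columns). Duplicate sample ids or gene symbols and
#' non-numeric cells are errors naming the location.
#'
#' @param path TSV or GCT file
#' @return numeric matrix with gene rownames and sample colnames
#' @export
readExpressionMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#1.2")) 2L else 0L
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (skip > 0L) df[["Description"]] <- NULL
  genes <- as.character(df[[1]])
  samples <- colnames(df)[-1]
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  colnames(df) <- samples
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop("non-numeric expression value at data row ", bad[1],
           ", column '", colnames(df)[j], "'")
    df[[j]] <- v
  }
  m <- as.matrix(df)
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV (first column = gene symbol)
#' @param m numeric matrix with dimnames
#' @param path output file
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(gene = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a clinical table (CSV)
#'
#' Requires columns id, time_months, event; extra columns are carried as
#' covariates. Non-positive times, non-0/1 events and duplicate ids are
#' errors naming the row.
#'
#' @param path CSV file
#' @return data.frame
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.delim(path, sep = ",", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("id", "time_months", "event")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("clinical table missing column(s): ",
         paste(missing, collapse = ", "))
  dup <- which(duplicated(df$id))
  if (length(dup)) stop("duplicate id at row ", dup[1], ": ", df$id[dup[1]])
  bad <- which(!is.finite(df$time_months) | df$time_months <= 0)
  if (length(bad))
    stop("non-positive time_months at row ", bad[1], " (id ",
         df$id[bad[1]], ")")
  bad <- which(!df$event %in% c(0, 1))
  if (length(bad))
    stop("event not 0/1 at row ", bad[1], " (id ", df$id[bad[1]], ")")
  df
}

#' Read a TLS event table (CSV: case_id, x_mm, y_mm, maturation)
#' @param path CSV file
#' @return data.frame
#' @export
readTLSEvents <- function(path) {
  df <- utils::read.delim(path, sep = ",", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("case_id", "x_mm", "y_mm", "maturation")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("event table missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!df$maturation %in% .maturation_levels)
  if (length(bad))
    stop("unknown maturation at row ", bad[1], ": ",
         df$maturation[bad[1]])
  df
}

#' Read an mIF cell table (CSV)
#'
#' Expects case_id, x_mm, y_mm, compartment_region, compartment_context and
#' one intensity column per panel marker.
#'
#' @param path CSV file
#' @return data.frame
#' @export
readCellTable <- function(path) {
  df <- utils::read.delim(path, sep = ",", check.names = FALSE,
                          stringsAsFactors = FALSE)
  .check_cells(df)
  for (m in .mif_markers) {
    bad <- which(!is.finite(df[[m]]) | df[[m]] < 0)
    if (length(bad))
      stop("invalid intensity for ", m, " at row ", bad[1])
  }
  df
}

#' Write a cell table as CSV
#' @param cells data.frame
#' @param path output file
#' @export
writeCellTable <- function(cells, path) {
  utils::write.table(cells, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
}

#' Read region polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features tagged with a
#' \code{role} property; the \code{tumour_boundary} feature is required,
#' an optional \code{tissue} feature gives the tissue extent.
#'
#' @param path GeoJSON file
#' @return list with \code{boundary} (n x 2 matrix), \code{tissueExtent}
#'   (matrix or NULL) and \code{band_width_mm} when recorded
#' @export
readRegionsGeoJSON <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  polys <- list(); band <- NULL
  for (f in gj$features) {
    role <- f$properties$role
    if (is.null(role)) next
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature with role '", role, "' is not a Polygon")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    polys[[role]] <- m
    if (!is.null(f$properties$band_width_mm))
      band <- f$properties$band_width_mm
  }
  if (is.null(polys$tumour_boundary))
    stop("GeoJSON has no feature with role 'tumour_boundary'")
  list(boundary = .normalize_polygon(polys$tumour_boundary, "boundary"),
       tissueExtent = if (!is.null(polys$tissue))
         .normalize_polygon(polys$tissue, "tissue") else NULL,
       band_width_mm = band)
}

#' Write region polygons to GeoJSON
#' @param boundary n x 2 matrix
#' @param path output file
#' @param tissueExtent optional n x 2 matrix
#' @param bandWidth optional band width recorded as a property
#' @export
writeRegionsGeoJSON <- function(boundary, path, tissueExtent = NULL,
                                bandWidth = NULL) {
  close_ring <- function(m) {
    m <- as.matrix(m)
    rbind(m, m[1, , drop = FALSE])
  }
  feat <- function(m, role) {
    props <- list(role = role)
    if (!is.null(bandWidth)) props$band_width_mm <- bandWidth
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(
                           seq_len(nrow(close_ring(m))),
                           function(i) as.numeric(close_ring(m)[i, ])))))
  }
  features <- list(feat(boundary, "tumour_boundary"))
  if (!is.null(tissueExtent))
    features <- c(features, list(feat(tissueExtent, "tissue")))
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = features),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write a simulated cohort to disk
#'
#' Writes the analysis-facing expression TSV and clinical CSV, and the
#' hidden truth (latent abundance) to a separate sidecar JSON that the
#' analysis never reads.
#'
#' @param cohort a \linkS4class{TLSCohort}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, "expression.tsv")
  p_clin <- file.path(dir, "clinical.csv")
  p_truth <- file.path(dir, "truth.json")
  writeExpressionMatrix(SummarizedExperiment::assay(cohort, "exprs"),
                        p_expr)
  paths <- p_expr
  sv <- survivalData(cohort)
  if (!is.null(sv)) {
    utils::write.table(sv, p_clin, sep = ",", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p_clin)
  }
  tr <- latentTruth(cohort)
  if (!is.null(tr)) {
    jsonlite::write_json(tr["latent"], p_truth, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p_truth)
  }
  invisible(paths)
}

#' Write a score table as TSV (sample, signature, score, label)
#' @param scores score table from \code{\link{ssgseaScore}}
#' @param path output file
#' @export
writeScoreTable <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
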