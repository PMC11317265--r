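# Small shared helpers: gene-symbol normalization, significance stars,
# polygon arithmetic.

# Protein-name aliases for signature genes given as surface markers.
.symbol_aliases <- c(CD21 = "CR2", CD23 = "FCER2")

#' Normalize gene symbols
#'
#' Uppercases, strips surrounding whitespace and applies a small built-in
#' protein-name alias table (CD21 -> CR2, CD23 -> FCER2), so signatures
#' quoted with surface-marker names match HGNC-style expression rownames.
#'
#' @param x character vector of gene symbols
#' @return normalized character vector
#' @examples normalizeGeneSymbols(c(" cd21", "CXCL13"))
#' @export
normalizeGeneSymbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  hit <- x %in% names(.symbol_aliases)
  x[hit] <- unname(.symbol_aliases[x[hit]])
  x
}

#' Significance stars for a p-value
#'
#' Standard four-level annotation: \code{*} p < 0.05, \code{**} p < 0.01,
#' \code{***} p < 0.001, \code{****} p < 0.0001; empty string otherwise.
#'
#' @param p numeric vector of p-values
#' @return character vector of star annotations
#' @examples pStars(c(0.2, 0.003, 1e-5))
#' @export
pStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

# Signed shoelace area; positive for counter-clockwise vertex order.
.polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a simple polygon
#' @param poly n x 2 vertex matrix (mm)
#' @return area in mm^2 (always positive)
#' @export
polygonArea <- function(poly) abs(.polygon_signed_area(as.matrix(poly)))

# Ensure counter-clockwise orientation and drop a duplicated closing vertex.
.normalize_polygon <- function(poly, what = "polygon") {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L) stop(what, " must be an n x 2 matrix")
  n <- nrow(poly)
  if (n >= 2L && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop(what, " needs at least 3 distinct vertices")
  storage.mode(poly) <- "double"
  if (!cpp_polygon_is_simple(poly))
    stop(what, " is self-intersecting")
  if (.polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

# deterministic seed handling: run expr under a local RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
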