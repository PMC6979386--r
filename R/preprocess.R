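#' Quality-control filter on cells
#'
#' Removes cells with fewer than `min_genes` expressed (nonzero) genes or
#' with more than `max_mito_frac` of their counts coming from mitochondrial
#' genes. Both comparisons are strict, so cells exactly at the boundary are
#' retained. The gene axis is unchanged.
#'
#' @param x a [screen_matrix] with layer `raw_counts`.
#' @param mito_prefix character vector of gene-name prefixes identifying
#'   mitochondrial genes.
#' @param min_genes minimum number of expressed genes per retained cell.
#' @param max_mito_frac maximum mitochondrial count fraction per cell.
#' @return The filtered [screen_matrix]; a `qc_report` attribute records the
#'   cell counts before and after.
#' @export
qc_filter <- function(x, mito_prefix = c("MT-", "mt-"), min_genes = 500,
                      max_mito_frac = 0.10) {
  stopifnot(inherits(x, "screen_matrix"))
  if (x$layer != "raw_counts") {
    stop("qc_filter() expects the raw_counts layer", call. = FALSE)
  }
  m <- raw_counts(x)
  n_expressed <- Matrix::rowSums(m > 0)
  total <- Matrix::rowSums(m)
  is_mito <- Reduce(`|`, lapply(mito_prefix, function(p)
    startsWith(x$gene_ids, p)))
  mito_frac <- if (any(is_mito)) {
    Matrix::rowSums(m[, is_mito, drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, length(total))
  }
  keep <- !(n_expressed < min_genes) & !(mito_frac > max_mito_frac)
  if (!any(keep)) {
    stop("qc_filter() removed every cell; review min_genes/max_mito_frac ",
         "thresholds", call. = FALSE)
  }
  report <- list(cells_before = length(keep), cells_after = sum(keep),
                 min_genes = min_genes, max_mito_frac = max_mito_frac)
  message("qc_filter: retained ", report$cells_after, " of ",
          report$cells_before, " cells")
  out <- subset_cells(x, which(keep))
  attr(out, "qc_report") <- report
  out
}

#' Normalize and scale an expression matrix
#'
#' The conventional single-cell pipeline: per-cell depth normalization to a
#' fixed total, log1p transform, then per-gene centering and unit-variance
#' scaling. Zero-variance genes scale to all-zero columns. The raw count
#' layer is kept so downstream code can query true dropout zeros. Each step
#' can be toggled; rank-based downstream analysis is invariant to any
#' per-cell monotone normalization applied uniformly, so the toggles mainly
#' matter for the regression model.
#'
#' @param x a [screen_matrix] with layer `raw_counts`.
#' @param scale_factor per-cell total after depth normalization.
#' @param do_normalize,do_log,do_scale toggles for the three steps.
#' @return The input with a `scaled` layer added and `layer = "scaled"`.
#' @export
normalize_and_scale <- function(x, scale_factor = 1e4, do_normalize = TRUE,
                                do_log = TRUE, do_scale = TRUE) {
  stopifnot(inherits(x, "screen_matrix"))
  if (is.null(x$raw)) {
    stop("normalize_and_scale() expects raw counts", call. = FALSE)
  }
  m <- as.matrix(raw_counts(x))
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("cell '", x$cell_ids[which(totals == 0)[1]],
         "' has zero total count; run qc_filter() first", call. = FALSE)
  }
  if (do_normalize) m <- m / totals * scale_factor
  if (do_log) m <- log1p(m)
  if (do_scale) {
    mu <- colMeans(m)
    sdev <- apply(m, 2, stats::sd)
    m <- sweep(m, 2, mu, `-`)
    nz <- sdev > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sdev[nz], `/`)
    m[, !nz] <- 0
  }
  dimnames(m) <- list(x$cell_ids, x$gene_ids)
  x$scaled <- m
  x$layer <- "scaled"
  x
}

# log1p depth-normalized layer, computed on demand (for raw-flavoured
# signature scoring)
normalized_values <- function(x, scale_factor = 1e4) {
  m <- as.matrix(raw_counts(x))
  totals <- pmax(rowSums(m), 1)
  log1p(m / totals * scale_factor)
}
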