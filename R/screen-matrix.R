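#' Expression container for a single-cell screen
#'
#' A `screen_matrix` holds a cells-by-genes expression matrix together with
#' its barcode and gene axes. Raw UMI counts are kept as a sparse layer even
#' after scaling, because the rank-based test needs to know which cells have
#' a true zero count (dropout) for the marker being ranked.
#'
#' @param values cells x genes numeric matrix (dense or sparse).
#' @param cell_ids character vector of unique cell barcodes (row axis).
#' @param gene_ids character vector of unique gene symbols (column axis).
#' @param layer one of `"raw_counts"`, `"normalized"`, `"scaled"`.
#'
#' @return An object of class `screen_matrix` with fields `raw` (sparse
#'   counts, present when constructed from counts), `scaled` (dense matrix or
#'   `NULL`), `cell_ids`, `gene_ids` and `layer`.
#' @export
screen_matrix <- function(values, cell_ids, gene_ids,
                          layer = c("raw_counts", "normalized", "scaled")) {
  layer <- match.arg(layer)
  if (anyDuplicated(cell_ids)) {
    dup <- cell_ids[duplicated(cell_ids)][1]
    stop("duplicate cell barcode: ", dup, call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    stop("duplicate gene identifier: ", dup, call. = FALSE)
  }
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    stop("matrix dimensions (", nrow(values), " x ", ncol(values),
         ") do not match axis lengths (", length(cell_ids), " cells, ",
         length(gene_ids), " genes)", call. = FALSE)
  }
  x <- list(raw = NULL, scaled = NULL,
            cell_ids = as.character(cell_ids),
            gene_ids = as.character(gene_ids),
            layer = layer)
  if (layer == "raw_counts") {
    v <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    if (any(v@x < 0) || any(v@x != round(v@x))) {
      stop("raw_counts layer must contain non-negative integers", call. = FALSE)
    }
    dimnames(v) <- list(x$cell_ids, x$gene_ids)
    x$raw <- v
  } else {
    v <- as.matrix(values)
    dimnames(v) <- list(x$cell_ids, x$gene_ids)
    x$scaled <- v
  }
  structure(x, class = "screen_matrix")
}

#' @export
dim.screen_matrix <- function(x) {
  c(length(x$cell_ids), length(x$gene_ids))
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat("<screen_matrix> ", length(x$cell_ids), " cells x ",
      length(x$gene_ids), " genes; layer: ", x$layer, "\n", sep = "")
  layers <- c(if (!is.null(x$raw)) "raw_counts",
              if (!is.null(x$scaled)) x$layer[x$layer != "raw_counts"])
  cat("  layers stored:",
      paste(c(if (!is.null(x$raw)) "raw_counts",
              if (!is.null(x$scaled)) "scaled"), collapse = ", "), "\n")
  invisible(x)
}

#' Access the raw count layer
#' @param x a [screen_matrix].
#' @return Sparse cells x genes count matrix.
#' @export
raw_counts <- function(x) {
  stopifnot(inherits(x, "screen_matrix"))
  if (is.null(x$raw)) stop("no raw_counts layer stored", call. = FALSE)
  x$raw
}

#' Access the scaled layer
#' @param x a [screen_matrix].
#' @return Dense cells x genes matrix of per-gene z-scores.
#' @export
scaled_values <- function(x) {
  stopifnot(inherits(x, "screen_matrix"))
  if (is.null(x$scaled)) {
    stop("no scaled layer: run normalize_and_scale() first", call. = FALSE)
  }
  x$scaled
}

# subset cells, keeping all layers aligned
subset_cells <- function(x, keep) {
  x$cell_ids <- x$cell_ids[keep]
  if (!is.null(x$raw)) x$raw <- x$raw[keep, , drop = FALSE]
  if (!is.null(x$scaled)) x$scaled <- x$scaled[keep, , drop = FALSE]
  x
}
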