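# Readers and writers for the screen's standard file formats. All readers
# accept gzip-compressed files transparently.

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Read a single-cell expression matrix
#'
#' Supports the 10x-style MatrixMarket triplet (a `matrix.mtx` with sibling
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, genes in rows) and dense
#' delimited text. The returned object carries the `raw_counts` layer.
#'
#' @param path for `mtx_triplet`, the `.mtx` file or the directory holding
#'   the triplet; for `dense_tsv`, the text file.
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @param orientation for dense text only: `"genes_in_rows"` (default; rows
#'   are genes, columns are cells) or `"cells_in_rows"`.
#' @return A [screen_matrix] with layer `raw_counts`.
#' @export
read_expression_matrix <- function(path,
                                   format = c("mtx_triplet", "dense_tsv"),
                                   orientation = c("genes_in_rows",
                                                   "cells_in_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx_triplet") {
    read_mtx_triplet(path)
  } else {
    read_dense_matrix(path, orientation)
  }
}

find_sibling <- function(dir, stems) {
  for (s in stems) {
    for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(s, ext))
      if (file.exists(f)) return(f)
    }
  }
  stop("missing sibling file (looked for ",
       paste(stems, collapse = ", "), ") in ", dir, call. = FALSE)
}

read_mtx_triplet <- function(path) {
  if (dir.exists(path)) {
    mtx <- find_sibling(path, c("matrix.mtx"))
    dir <- path
  } else {
    mtx <- path
    dir <- dirname(path)
  }
  m <- Matrix::readMM(open_maybe_gz(mtx))
  feat_file <- find_sibling(dir, c("features.tsv", "genes.tsv"))
  bc_file <- find_sibling(dir, c("barcodes.tsv"))
  feats <- utils::read.table(open_maybe_gz(feat_file), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
  bcs <- utils::read.table(open_maybe_gz(bc_file), sep = "\t",
                           header = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")[[1]]
  gene_ids <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (nrow(m) != length(gene_ids)) {
    stop("triplet header declares ", nrow(m), " genes but features file has ",
         length(gene_ids), call. = FALSE)
  }
  if (ncol(m) != length(bcs)) {
    stop("triplet header declares ", ncol(m), " cells but barcodes file has ",
         length(bcs), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    warning("duplicate gene symbols made unique with make.unique()")
    gene_ids <- make.unique(gene_ids)
  }
  # 10x dialect stores genes x cells; internal orientation is cells x genes
  screen_matrix(Matrix::t(m), bcs, gene_ids, layer = "raw_counts")
}

read_dense_matrix <- function(path, orientation) {
  tab <- utils::read.table(open_maybe_gz(path), sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE, quote = "",
                           comment.char = "")
  m <- as.matrix(tab)
  if (orientation == "genes_in_rows") m <- t(m)
  screen_matrix(m, rownames(m), colnames(m), layer = "raw_counts")
}

#' Write an expression matrix as dense TSV
#'
#' Inverse of `read_expression_matrix(format = "dense_tsv")`; genes in rows.
#'
#' @param x a [screen_matrix]; the raw layer is written.
#' @param path output file.
#' @export
write_dense_matrix <- function(x, path) {
  m <- t(as.matrix(raw_counts(x)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set (GMT) file
#'
#' Standard GMT: per line a set name, a description (discarded), then
#' tab-separated gene symbols. Order is preserved; duplicate symbols within
#' a line are dropped with a warning.
#'
#' @param path GMT file (optionally gzipped).
#' @return Named list of character vectors (a signature set).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(open_maybe_gz(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", fields[[1]], "' deduplicated")
      genes <- genes[!duplicated(genes)]
    }
    out[[fields[[1]]]] <- genes
  }
  out
}

#' Read cluster labels
#'
#' Two-column delimited text (barcode, cluster), no header required; a
#' header line is detected when the first row matches `cell`/`barcode`.
#'
#' @param path delimited file.
#' @return A tibble with columns `cell`, `cluster`.
#' @export
read_cluster_labels <- function(path) {
  tab <- utils::read.table(open_maybe_gz(path), sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (tolower(tab[1, 1]) %in% c("cell", "barcode", "cell_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  tibble::tibble(cell = as.character(tab[[1]]),
                 cluster = as.character(tab[[2]]))
}
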