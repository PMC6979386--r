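# Virtual-FACS phenotyping: score cells on a marker signature, assemble
# FDR-thresholded target-marker-phenotype networks from engine results,
# and draw random marker panels for false-positive evaluation.

#' Per-cell gene-signature score
#'
#' The arithmetic mean of the signature genes' expression per cell. By
#' default the scaled layer is averaged (means of z-scores), matching the
#' pipeline's scaled input; `layer = "normalized"` averages the log1p
#' depth-normalized counts instead. Absent genes are dropped with a
#' warning.
#'
#' @param x a [screen_matrix].
#' @param genes character vector of signature gene ids.
#' @param layer `"scaled"` (default) or `"normalized"`.
#' @return Tibble (cell, score).
#' @export
signature_score <- function(x, genes, layer = c("scaled", "normalized")) {
  layer <- match.arg(layer)
  present <- intersect(genes, x$gene_ids)
  if (!length(present)) {
    stop("none of the signature genes are present", call. = FALSE)
  }
  if (length(present) < length(unique(genes))) {
    warning(length(unique(genes)) - length(present),
            " signature gene(s) absent and dropped")
  }
  m <- if (layer == "scaled") scaled_values(x) else normalized_values(x)
  tibble::tibble(cell = x$cell_ids,
                 score = rowMeans(m[, present, drop = FALSE]))
}

#' Build a target-marker-phenotype network
#'
#' One edge per (target, marker) association passing the FDR cutoff. A
#' rank-test result contributes an edge when `min(fdr_neg, fdr_pos)` beats
#' the cutoff; a table with a single `fdr` column (e.g. [query_marker()]
#' output with a `marker` column added) uses that column directly. The edge
#' sign follows the selection score. Edge order is deterministic (target,
#' then marker).
#'
#' @param results an `rra_result`, or a data frame with columns `target`,
#'   `marker`, `score`, `fdr`, or a list of such objects.
#' @param fdr_cutoff edges require FDR strictly below this value, in
#'   `(0, 1]`.
#' @param phenotype_labels optional named character vector mapping marker
#'   to phenotype label; unmapped markers keep their own name.
#' @param condition free-text condition label stamped on every edge.
#' @return Tibble of class `phenotype_network` with columns `target`,
#'   `marker`, `phenotype`, `condition`, `sign`, `score`, `fdr`.
#' @export
build_network <- function(results, fdr_cutoff = 0.1,
                          phenotype_labels = NULL, condition = "default") {
  if (!(fdr_cutoff > 0 && fdr_cutoff <= 1)) {
    stop("fdr_cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (inherits(results, "rra_result") || is.data.frame(results)) {
    results <- list(results)
  }
  edges <- purrr::map_dfr(results, function(res) {
    df <- tibble::as_tibble(res)
    if (all(c("fdr_neg", "fdr_pos") %in% names(df))) {
      df$fdr <- pmin(df$fdr_neg, df$fdr_pos)
    }
    stopifnot(all(c("target", "marker", "score", "fdr") %in% names(df)))
    df[df$fdr < fdr_cutoff,
       c("target", "marker", "score", "fdr"), drop = FALSE]
  })
  edges$phenotype <- edges$marker
  if (!is.null(phenotype_labels)) {
    hit <- edges$marker %in% names(phenotype_labels)
    edges$phenotype[hit] <- unname(phenotype_labels[edges$marker[hit]])
  }
  edges$condition <- condition
  edges$sign <- ifelse(edges$score < 0, "-", "+")
  out <- edges[order_radix(edges$target, edges$marker),
               c("target", "marker", "phenotype", "condition", "sign",
                 "score", "fdr")]
  structure(out, class = c("phenotype_network", class(tibble::tibble())))
}

#' Write a network as edge TSV and GraphML
#'
#' @param edges a [build_network()] result.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @export
write_network <- function(edges, prefix) {
  utils::write.table(as.data.frame(edges), paste0(prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("target", "marker", "phenotype", "condition", "sign",
                "score", "fdr")],
      directed = TRUE)
    igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  }
  invisible(prefix)
}

#' Random marker panel
#'
#' Uniform sample of marker genes without replacement, the driver for the
#' false-positive evaluation workflow (shuffle identities, pick random
#' markers, count spurious associations).
#'
#' @param genes candidate gene axis.
#' @param k panel size (default 50).
#' @param seed integer seed; the draw is reproducible.
#' @return Character vector of `k` gene ids.
#' @export
random_marker_panel <- function(genes, k = 50, seed = 1) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > length(genes)) stop("k exceeds the number of candidate genes",
                              call. = FALSE)
  withr::with_seed(derive_seed(seed, 0L), sample(genes, k))
}
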