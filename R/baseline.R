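#' Cluster-enrichment baseline
#'
#' The conventional "enrichment by clustering" analysis the rank and
#' regression engines are compared against: for every (target, cluster)
#' pair, a 2x2 contingency table (in/out of cluster x carrying/not carrying
#' the target) is tested by chi-squared without continuity correction, the
#' p-values are Benjamini-Hochberg adjusted across all pairs, and a pair is
#' called enriched when the target's cells make up more than `min_frac` of
#' the cluster and the adjusted p-value is below `fdr_cutoff`. Cells
#' carrying several targets count once per carried target. Degenerate
#' tables (a zero margin) are skipped with p = 1.
#'
#' @param labels tibble (cell, cluster), e.g. from [read_cluster_labels()];
#'   at least two distinct clusters are required.
#' @param identity a [cell_identity].
#' @param min_frac minimum share of the cluster made of target cells.
#' @param fdr_cutoff adjusted-p threshold for the enrichment call.
#' @param correct apply the Yates continuity correction (off by default).
#' @return Tibble with one row per (target, cluster): `target`, `cluster`,
#'   `n_target_in_cluster`, `cluster_size`, `frac`, `chi2_p`, `adj_p`,
#'   `enriched`.
#' @export
cluster_enrichment <- function(labels, identity, min_frac = 0.20,
                               fdr_cutoff = 0.25, correct = FALSE) {
  ntc <- ntc_label(identity)
  cells <- intersect(labels$cell, unique(identity$cell))
  if (!length(cells)) stop("no overlap between labeled and identity cells",
                           call. = FALSE)
  labels <- labels[labels$cell %in% cells, , drop = FALSE]
  if (length(unique(labels$cluster)) < 2) {
    stop("at least two clusters are required", call. = FALSE)
  }
  df <- identity[identity$cell %in% cells & identity$target != ntc, ,
                 drop = FALSE]
  targets <- sort(unique(df$target), method = "radix")
  clusters <- sort(unique(labels$cluster), method = "radix")
  n_total <- length(cells)
  cl_of <- stats::setNames(labels$cluster, labels$cell)
  cluster_size <- table(labels$cluster)

  grid <- tidyr::expand_grid(target = targets, cluster = clusters)
  res <- purrr::pmap_dfr(grid, function(target, cluster) {
    tcells <- unique(df$cell[df$target == target])
    a <- sum(cl_of[tcells] == cluster)               # target, in cluster
    csize <- as.integer(cluster_size[[cluster]])
    b <- csize - a                                   # other cells in cluster
    c_ <- length(tcells) - a                         # target cells elsewhere
    d <- n_total - csize - c_
    tab <- matrix(c(a, b, c_, d), 2)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      1
    } else {
      suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
    }
    tibble::tibble(target = target, cluster = cluster,
                   n_target_in_cluster = a, cluster_size = csize,
                   frac = a / csize, chi2_p = p)
  })
  res$adj_p <- benjamini_hochberg(res$chi2_p)
  res$enriched <- res$frac > min_frac & res$adj_p < fdr_cutoff
  res
}
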