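# Robust rank aggregation engine: rank cells by a marker, score each
# perturbation's enrichment toward high (positive selection) or low
# (negative selection) marker expression with beta order-statistic
# p-values, truncating dropout cells out of the tested tail.

#' Rank cells by a marker's expression
#'
#' Ranks all cells by the scaled expression of a single gene or by a
#' gene-signature score (the per-cell mean of member z-scores). Rank 1 is
#' the highest expression for `direction = "descending"` (the positive
#' selection orientation) and the lowest for `"ascending"`. Ties, including
#' the block of dropout zeros, are broken deterministically by barcode.
#' Dropout flags come from the raw count layer: a cell is flagged when its
#' raw count for the marker gene is zero, or, for a signature, when all
#' member genes have zero raw counts.
#'
#' @param x a [screen_matrix] with raw and scaled layers.
#' @param marker a gene id, or a named list of one character vector of gene
#'   ids (a signature).
#' @param direction `"descending"` or `"ascending"`.
#' @return A list of class `cell_ranking`: `marker_id`, `direction`,
#'   `ranks` (named permutation of `1..M`), `zero_flags`, `M`, and `alpha`,
#'   the fraction of cells with nonzero marker count.
#' @export
rank_cells <- function(x, marker, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  sc <- scaled_values(x)
  if (is.character(marker) && length(marker) == 1) {
    if (!marker %in% x$gene_ids) {
      near <- utils::head(x$gene_ids[startsWith(toupper(x$gene_ids),
                                                toupper(substr(marker, 1, 3)))],
                          5)
      stop("marker '", marker, "' not found",
           if (length(near)) paste0("; near matches: ",
                                    paste(near, collapse = ", ")),
           call. = FALSE)
    }
    expr <- sc[, marker]
    zero <- raw_counts(x)[, marker] == 0
    marker_id <- marker
  } else {
    genes <- unlist(marker, use.names = FALSE)
    marker_id <- names(marker)[1] %||% "signature"
    present <- intersect(genes, x$gene_ids)
    if (!length(present)) {
      stop("no signature gene present in the matrix", call. = FALSE)
    }
    if (length(present) < length(genes)) {
      warning(length(genes) - length(present),
              " signature gene(s) absent and dropped")
    }
    expr <- rowMeans(sc[, present, drop = FALSE])
    zero <- Matrix::rowSums(raw_counts(x)[, present, drop = FALSE] > 0) == 0
  }
  M <- length(expr)
  ord <- if (direction == "descending") {
    order_radix(-expr, x$cell_ids)
  } else {
    order_radix(expr, x$cell_ids)
  }
  ranks <- integer(M)
  ranks[ord] <- seq_len(M)
  names(ranks) <- x$cell_ids
  zero <- as.logical(zero)
  names(zero) <- x$cell_ids
  structure(list(marker_id = marker_id, direction = direction, ranks = ranks,
                 zero_flags = zero, M = M, alpha = mean(!zero)),
            class = "cell_ranking")
}

#' Beta order-statistic p-values
#'
#' Under the null, cell-rank percentiles are i.i.d. Uniform(0, 1), so the
#' k-th smallest of n percentiles follows Beta(k, n + 1 - k). The p-value
#' for the k-th order statistic at value `u` is the Beta CDF there,
#' equivalently the binomial tail `P(Binom(n, u) >= k)`.
#'
#' @param u non-decreasing vector of percentiles in `[0, 1]`.
#' @return Vector `p_k = pbeta(u_k, k, n + 1 - k)`.
#' @export
order_statistic_pvalues <- function(u) {
  if (is.unsorted(u)) stop("percentiles must be sorted", call. = FALSE)
  if (any(u < 0 | u > 1)) stop("percentiles must lie in [0, 1]",
                               call. = FALSE)
  n <- length(u)
  k <- seq_len(n)
  stats::pbeta(u, k, n + 1 - k)
}

#' Positive-selection rho
#'
#' On a descending ranking (highest marker expression first), computes the
#' minimal beta order-statistic p-value over the first `j` order statistics
#' of the target cells' rank percentiles, where `j` is the number of target
#' cells with nonzero marker count. Cells whose marker count dropped out
#' carry no evidence of high expression and are excluded; with `j = 0` the
#' score is 1.
#'
#' @param ranking a descending [rank_cells()] result.
#' @param target_cells barcodes (or positions) of the cells carrying the
#'   perturbation.
#' @return List with `rho` and `j`.
#' @export
rho_positive <- function(ranking, target_cells) {
  stopifnot(inherits(ranking, "cell_ranking"))
  if (ranking$direction != "descending") {
    stop("positive selection requires a descending ranking", call. = FALSE)
  }
  rho_truncated(ranking$ranks[target_cells],
                ranking$zero_flags[target_cells], ranking$M,
                side = "positive")
}

#' Negative-selection rho
#'
#' On an ascending ranking (lowest expression first) the dropout zeros of
#' the marker occupy the front of the list, so they cannot be separated
#' from true low expression. The first `j` target cells with zero marker
#' count are therefore excluded, and rho is the minimum over the remaining
#' order-statistic p-values `p_(j+1) .. p_(n)`; with all cells at zero the
#' score is 1.
#'
#' @param ranking_asc an ascending [rank_cells()] result.
#' @param target_cells barcodes (or positions) of the perturbed cells.
#' @return List with `rho` and `j` (the number of excluded zero-count
#'   cells).
#' @export
rho_negative <- function(ranking_asc, target_cells) {
  stopifnot(inherits(ranking_asc, "cell_ranking"))
  if (ranking_asc$direction != "ascending") {
    stop("negative selection requires an ascending ranking", call. = FALSE)
  }
  rho_truncated(ranking_asc$ranks[target_cells],
                ranking_asc$zero_flags[target_cells], ranking_asc$M,
                side = "negative")
}

# shared core for both orientations: sort the n percentiles, keep the
# order statistics on the nonzero side of the truncation, take the min
rho_truncated <- function(r, zero, M, side) {
  n <- length(r)
  if (!n) stop("target cell set is empty", call. = FALSE)
  u <- sort(r) / M
  k <- seq_len(n)
  p <- stats::pbeta(u, k, n + 1 - k)
  if (side == "positive") {
    j <- sum(!zero)
    if (j == 0) return(list(rho = 1, j = 0L))
    list(rho = min(p[seq_len(j)]), j = as.integer(j))
  } else {
    j <- sum(zero)
    if (j == n) return(list(rho = 1, j = as.integer(j)))
    list(rho = min(p[(j + 1):n]), j = as.integer(j))
  }
}

#' Signed selection score
#'
#' Combines the negative- and positive-selection p-values of one
#' perturbation on one marker into a single signed quantity:
#' `log(p_neg)` when `p_neg < p_pos` (knockout lowers the marker),
#' `-log(p_pos)` when `p_pos < p_neg`, and 0 at a tie. Natural logarithm;
#' p-values of zero are clamped to the permutation floor.
#'
#' @param p_neg,p_pos empirical p-values for negative/positive selection.
#' @param floor smallest attainable p-value, `1/(n_perm + 1)`.
#' @return Signed score vector.
#' @export
selection_score <- function(p_neg, p_pos, floor = NULL) {
  if (!is.null(floor)) {
    p_neg <- pmax(p_neg, floor)
    p_pos <- pmax(p_pos, floor)
  }
  dplyr::case_when(p_neg < p_pos ~ log(p_neg),
                   p_pos < p_neg ~ -log(p_pos),
                   TRUE ~ 0)
}

#' Rank-aggregation perturbation test
#'
#' For each perturbation target, tests whether its cells are enriched
#' toward high (positive selection) or low (negative selection) expression
#' of a marker gene or signature. Observed rho values are compared against
#' a permutation null in which whole sgRNA bundles are reassigned to cells,
#' preserving each target's cell count and each cell's multiplicity;
#' empirical p-values use the add-one estimator and are adjusted by
#' Benjamini-Hochberg across targets within each direction.
#'
#' Cells carrying several targets contribute to each of their targets' cell
#' sets; the rank test cannot separate co-occurring perturbations, so a
#' warning is issued for such screens (use the regression engine there).
#'
#' @param x a [screen_matrix] with raw and scaled layers.
#' @param identity a [cell_identity]; only cells present in `x` are used.
#' @param marker gene id or named single-signature list.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param include_ntc also score the non-targeting control pseudo-target.
#' @return A tibble of class `rra_result` with one row per target:
#'   `target`, `marker`, `n_cells`, `n_nonzero`, `rho_neg`, `rho_pos`,
#'   `p_neg`, `p_pos`, `fdr_neg`, `fdr_pos`, `score`. Attributes record
#'   `marker`, `n_perm`, `seed`, `M` and `alpha`.
#' @export
rra_test <- function(x, identity, marker, n_perm = 1000, seed = 1,
                     include_ntc = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  rk_desc <- rank_cells(x, marker, "descending")
  rk_asc <- rank_cells(x, marker, "ascending")
  M <- rk_desc$M
  sets <- target_cell_sets(identity, x$cell_ids, include_ntc = include_ntc)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " target(s) with no ranked cells dropped")
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no targets with ranked cells", call. = FALSE)
  moi <- table(identity$cell[identity$cell %in% x$cell_ids])
  if (any(moi > 1)) {
    warning("cells carry multiple sgRNAs; the rank test is not suitable ",
            "for high-MOI screens (consider the regression engine)")
  }

  K <- length(sets)
  sizes <- lengths(sets)
  all_idx <- unlist(sets, use.names = FALSE)
  gid <- rep.int(seq_len(K), sizes)
  seg_end <- cumsum(sizes)
  seg_start <- seg_end - sizes + 1L
  kk <- sequence(sizes)                      # order-statistic index within target
  nn <- rep.int(sizes, sizes)                # n per element
  rd <- rk_desc$ranks
  ra <- rk_asc$ranks
  zero <- unname(rk_desc$zero_flags)

  rho_round <- function(pos) {
    z <- zero[pos]
    # positive selection: sort descending-ranks within each target
    o <- order_radix(gid, rd[pos])
    pb <- stats::pbeta(rd[pos][o] / M, kk, nn + 1 - kk)
    jpos <- tabulate(gid[!z], nbins = K)
    pb[kk > jpos[gid]] <- Inf
    rpos <- vapply(seq_len(K), function(t)
      min(pb[seg_start[t]:seg_end[t]]), numeric(1))
    rpos[!is.finite(rpos)] <- 1
    # negative selection: ascending ranks, first j zero-count excluded
    o2 <- order_radix(gid, ra[pos])
    pb2 <- stats::pbeta(ra[pos][o2] / M, kk, nn + 1 - kk)
    jneg <- tabulate(gid[z], nbins = K)
    pb2[kk <= jneg[gid]] <- Inf
    rneg <- vapply(seq_len(K), function(t)
      min(pb2[seg_start[t]:seg_end[t]]), numeric(1))
    rneg[!is.finite(rneg)] <- 1
    list(pos = rpos, neg = rneg, j = jpos)
  }

  obs <- rho_round(all_idx)
  cnt_pos <- numeric(K)
  cnt_neg <- numeric(K)
  withr::with_seed(derive_seed(seed, 0L), {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(M)
      r <- rho_round(perm[all_idx])
      cnt_pos <- cnt_pos + (r$pos <= obs$pos)
      cnt_neg <- cnt_neg + (r$neg <= obs$neg)
    }
  })
  p_pos <- (1 + cnt_pos) / (1 + n_perm)
  p_neg <- (1 + cnt_neg) / (1 + n_perm)
  res <- tibble::tibble(
    target = names(sets),
    marker = rk_desc$marker_id,
    n_cells = as.integer(sizes),
    n_nonzero = obs$j,
    rho_neg = obs$neg,
    rho_pos = obs$pos,
    p_neg = p_neg,
    p_pos = p_pos,
    fdr_neg = benjamini_hochberg(p_neg),
    fdr_pos = benjamini_hochberg(p_pos),
    score = selection_score(p_neg, p_pos, floor = 1 / (n_perm + 1))
  )
  structure(res, class = c("rra_result", class(res)),
            marker = rk_desc$marker_id, n_perm = n_perm, seed = seed,
            M = M, alpha = rk_desc$alpha)
}

#' Write a rank-test result as delimited text
#'
#' One row per target with a provenance header recording the parameters
#' needed to reproduce the file.
#'
#' @param res an [rra_test()] result.
#' @param path output TSV.
#' @export
write_rra_result <- function(res, path) {
  hdr <- sprintf("# screenlink %s rra: marker=%s n_perm=%d seed=%d M=%d alpha=%.6f",
                 as.character(utils::packageVersion("screenlink")),
                 attr(res, "marker"), attr(res, "n_perm"),
                 attr(res, "seed"), attr(res, "M"), attr(res, "alpha"))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(as.data.frame(res), path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}
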