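# broom-style tidiers and default plots for the result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn rra_test tidy(): the per-target result tibble without the
#'   result class.
#' @param x an `rra_result`.
#' @param ... unused.
#' @method tidy rra_result
#' @export
tidy.rra_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "marker") <- NULL
  attr(out, "n_perm") <- NULL
  attr(out, "seed") <- NULL
  attr(out, "M") <- NULL
  attr(out, "alpha") <- NULL
  out
}

#' @describeIn rra_test glance(): one-row summary of the analysis.
#' @method glance rra_result
#' @export
glance.rra_result <- function(x, ...) {
  tibble::tibble(marker = attr(x, "marker"),
                 n_targets = nrow(x),
                 n_cells_ranked = attr(x, "M"),
                 alpha = attr(x, "alpha"),
                 n_perm = attr(x, "n_perm"),
                 seed = attr(x, "seed"),
                 n_sig_neg_05 = sum(x$fdr_neg < 0.05),
                 n_sig_pos_05 = sum(x$fdr_pos < 0.05))
}

#' @describeIn lr_test tidy(): long-format (target, gene, score, p,
#'   fdr_gene, fdr_target) tibble.
#' @param x a `score_matrix`.
#' @param ... unused.
#' @method tidy score_matrix
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble::tibble(target = rep(rownames(x$scores), times = ncol(x$scores)),
                 gene = rep(colnames(x$scores), each = nrow(x$scores)),
                 score = as.numeric(x$scores),
                 p = as.numeric(x$pval),
                 fdr_gene = as.numeric(x$fdr_gene),
                 fdr_target = as.numeric(x$fdr_target))
}

#' @describeIn lr_test glance(): one-row summary of the fit.
#' @method glance score_matrix
#' @export
glance.score_matrix <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x$scores), n_genes = ncol(x$scores),
                 lambda = x$lambda, n_perm = x$n_perm, seed = x$seed,
                 n_sig_gene_05 = sum(x$fdr_gene < 0.05))
}

#' @describeIn rra_test autoplot(): selection score against significance,
#'   one point per target.
#' @param object an `rra_result`.
#' @method autoplot rra_result
#' @export
autoplot.rra_result <- function(object, ...) {
  df <- tidy(object)
  df$min_fdr <- pmin(df$fdr_neg, df$fdr_pos)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = -log10(.data$min_fdr))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "selection score (log p, signed)",
                  y = "-log10 min FDR",
                  title = paste("marker:", attr(object, "marker"))) +
    ggplot2::theme_minimal()
}

#' @describeIn lr_test autoplot(): score heat map, targets by genes.
#' @param object a `score_matrix`.
#' @method autoplot score_matrix
#' @export
autoplot.score_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$target,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
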