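#' Power sweep over a screen-design axis
#'
#' Repeatedly simulates screens along one design axis and measures how
#' often each target's own-gene downregulation is recovered:
#' `fraction_detected` is the share of targets with significant negative
#' selection on their own gene (FDR below `fdr`, negative score), and, for
#' the regression engine, `fraction_top10` is the share of targets whose
#' own gene ranks within `top_n` of that target's transcriptome scan by
#' p-value. The axes emulate the determinants of screen power: baseline
#' target expression, multiplicity of infection at fixed total cells, and
#' cells per target.
#'
#' @param base_cfg a [sim_config()]; its `effects` define the implanted
#'   signal (typically [own_gene_effects()]).
#' @param axis `"target_expression"`, `"moi"` or `"cells_per_target"`.
#' @param levels monotone vector of axis values.
#' @param n_reps replicates per level (distinct seeds derived from
#'   `base_cfg$seed`).
#' @param engine `"rra"` or `"lr"`.
#' @param n_perm permutations per test.
#' @param fdr detection threshold on the adjusted p-value.
#' @param top_n rank cutoff for `fraction_top10`.
#' @return Tibble (level, rep, fraction_detected, fraction_top10);
#'   `fraction_top10` is `NA` for the rank engine, which scans one marker
#'   at a time rather than the whole transcriptome.
#' @export
power_sweep <- function(base_cfg, axis = c("target_expression", "moi",
                                           "cells_per_target"),
                        levels, n_reps = 10, engine = c("rra", "lr"),
                        n_perm = 500, fdr = 0.05, top_n = 10) {
  axis <- match.arg(axis)
  engine <- match.arg(engine)
  if (is.unsorted(levels) && is.unsorted(rev(levels))) {
    stop("levels must be monotone", call. = FALSE)
  }
  grid <- tidyr::expand_grid(level_idx = seq_along(levels),
                             rep = seq_len(n_reps))
  purrr::pmap_dfr(grid, function(level_idx, rep) {
    level <- levels[[level_idx]]
    cfg <- base_cfg
    cfg$seed <- derive_seed(base_cfg$seed, 997L * level_idx + rep)
    if (axis == "target_expression") {
      cfg$target_gene_mean <- level
    } else if (axis == "moi") {
      cfg$moi_mean <- level
    } else {
      cfg$n_cells <- ceiling(level * cfg$n_targets *
                               (1 + cfg$ntc_frac) / cfg$moi_mean)
    }
    sim <- simulate_screen(cfg)
    res <- screen_power_metrics(sim, engine, n_perm, fdr, top_n)
    tibble::tibble(level = level, rep = rep,
                   fraction_detected = res$detected,
                   fraction_top10 = res$top10)
  })
}

# own-gene detection metrics for one simulated screen
screen_power_metrics <- function(sim, engine, n_perm, fdr, top_n) {
  x <- normalize_and_scale(sim$raw)
  targets <- sim_gene_ids(sim$cfg$n_targets)
  if (engine == "rra") {
    det <- vapply(targets, function(t) {
      res <- suppressWarnings(rra_test(x, sim$identity, t, n_perm = n_perm,
                                       seed = sim$cfg$seed))
      row <- res[res$target == t, ]
      nrow(row) == 1 && row$fdr_neg < fdr && row$score < 0
    }, logical(1))
    list(detected = mean(det), top10 = NA_real_)
  } else {
    sm <- screen_lr(x, sim$identity, n_perm = n_perm, seed = sim$cfg$seed)
    present <- intersect(targets, rownames(sm$scores))
    det <- vapply(present, function(t) {
      sm$fdr_gene[t, t] < fdr && sm$scores[t, t] < 0
    }, logical(1))
    top10 <- vapply(present, function(t) {
      ord <- order(sm$pval[t, ], -abs(sm$scores[t, ]))
      match(t, colnames(sm$pval)[ord]) <= top_n
    }, logical(1))
    list(detected = mean(det), top10 = mean(top10))
  }
}

#' Plot a power sweep
#'
#' Detection fraction (and, where available, top-rank fraction) against the
#' swept axis level, with per-level means over replicates.
#'
#' @param sweep a [power_sweep()] result.
#' @return A ggplot object.
#' @export
plot_power_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("fraction_detected", "fraction_top10"),
                              names_to = "metric", values_to = "fraction")
  long <- long[!is.na(long$fraction), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$level),
                                     y = .data$fraction,
                                     colour = .data$metric)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.5) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$metric),
                          fun = mean, geom = "line") +
    ggplot2::labs(x = "axis level", y = "fraction of targets") +
    ggplot2::theme_minimal()
}
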