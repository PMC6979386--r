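# Evaluation studies: reusable drivers for the package's statistical
# claims (false-positive control, parameter recovery, power determinants,
# engine contrast). Each study simulates its own inputs from a seed and
# measures the result by running the engines, so every reported number is
# recomputed at call time.

#' False-positive evaluation on shuffled-label null screens
#'
#' Simulates effects-null screens, shuffles the cell-identity labels, draws
#' a random marker panel, runs one engine on every marker and counts
#' (target, marker) pairs called significant at `fdr` — the false-positive
#' workflow for permuted screens with randomly selected expression markers.
#'
#' @param engine `"rra"` or `"lr"`.
#' @param n_seeds number of independent null screens.
#' @param n_cells,n_genes,n_targets screen dimensions.
#' @param n_markers random marker panel size.
#' @param n_perm permutations per test.
#' @param fdr significance cutoff on the adjusted p-value.
#' @param seed base seed.
#' @return Tibble (seed, n_sig_pairs, n_pairs_tested).
#' @export
evaluate_false_positives <- function(engine = c("rra", "lr"), n_seeds = 10,
                                     n_cells = 200, n_genes = 100,
                                     n_targets = 20, n_markers = 50,
                                     n_perm = 500, fdr = 0.05, seed = 1) {
  engine <- match.arg(engine)
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                      n_targets = n_targets, effects = NULL,
                      seed = derive_seed(seed, 101L * s))
    sim <- simulate_screen(cfg)
    # belt and braces: the screen has no implanted effects, and the labels
    # are shuffled on top of that
    plan <- permutation_plan(1, derive_seed(seed, 211L * s))
    identity <- permute_identity(sim$identity, plan, 1)
    x <- normalize_and_scale(sim$raw)
    markers <- random_marker_panel(x$gene_ids, n_markers,
                                   seed = derive_seed(seed, 307L * s))
    if (engine == "rra") {
      n_sig <- sum(vapply(markers, function(m) {
        res <- suppressWarnings(rra_test(x, identity, m, n_perm = n_perm,
                                         seed = derive_seed(seed, 401L * s)))
        sum(pmin(res$fdr_neg, res$fdr_pos) < fdr)
      }, numeric(1)))
      n_tested <- length(markers) * n_targets
    } else {
      sm <- screen_lr(x, identity, n_perm = n_perm,
                      seed = derive_seed(seed, 401L * s))
      cols <- intersect(markers, colnames(sm$fdr_target))
      n_sig <- sum(sm$fdr_target[, cols] < fdr)
      n_tested <- length(cols) * nrow(sm$fdr_target)
    }
    tibble::tibble(seed = s, n_sig_pairs = n_sig, n_pairs_tested = n_tested)
  })
}

#' Own-gene knockdown recovery by the rank engine
#'
#' Simulates screens where each target downregulates only its own gene and
#' asks, per seed, whether the focal target's negative selection on its own
#' gene is detected (FDR below `fdr`, negative selection score).
#'
#' @param n_seeds replicate screens.
#' @param multiplier implanted own-gene effect.
#' @param cells_per_target expected perturbed cells per target.
#' @param n_targets,n_genes screen dimensions.
#' @param n_perm,fdr test settings.
#' @param seed base seed.
#' @return Tibble (seed, detected, fdr_neg, score).
#' @export
evaluate_recovery <- function(n_seeds = 20, multiplier = 0.3,
                              cells_per_target = 100, n_targets = 4,
                              n_genes = 50, n_perm = 1000, fdr = 0.05,
                              seed = 1) {
  ntc_frac <- 0.1
  n_cells <- ceiling(cells_per_target * n_targets / (1 - ntc_frac))
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                      n_targets = n_targets,
                      effects = own_gene_effects(n_targets, multiplier),
                      ntc_frac = ntc_frac, seed = derive_seed(seed, 53L * s))
    sim <- simulate_screen(cfg)
    x <- normalize_and_scale(sim$raw)
    res <- suppressWarnings(rra_test(x, sim$identity, "G001",
                                     n_perm = n_perm,
                                     seed = derive_seed(seed, 67L * s)))
    row <- res[res$target == "G001", ]
    tibble::tibble(seed = s,
                   detected = row$fdr_neg < fdr & row$score < 0,
                   fdr_neg = row$fdr_neg, score = row$score)
  })
}

#' Top-rank fraction at low versus high multiplicity of infection
#'
#' At a fixed total cell budget, compares how often each target's own gene
#' ranks among the strongest hits of its regression transcriptome scan
#' under two MOI regimes. Higher MOI gives every target more carrier cells
#' and hence more statistical power.
#'
#' @param n_seeds paired replicates.
#' @param moi_levels the two MOI means compared (low, high).
#' @param n_cells total cells per screen (fixed across regimes).
#' @param n_targets,n_genes screen dimensions.
#' @param multiplier implanted own-gene effect.
#' @param n_perm permutations for the regression test.
#' @param top_n rank cutoff.
#' @param seed base seed.
#' @return Tibble (seed, moi, fraction_top10).
#' @export
evaluate_moi_power <- function(n_seeds = 10, moi_levels = c(1, 4),
                               n_cells = 150, n_targets = 10, n_genes = 100,
                               multiplier = 0.5, n_perm = 200, top_n = 10,
                               seed = 1) {
  grid <- tidyr::expand_grid(s = seq_len(n_seeds), moi = moi_levels)
  purrr::pmap_dfr(grid, function(s, moi) {
    cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                      n_targets = n_targets, moi_mean = moi,
                      effects = own_gene_effects(n_targets, multiplier),
                      seed = derive_seed(seed, 41L * s))
    sim <- simulate_screen(cfg)
    x <- normalize_and_scale(sim$raw)
    sm <- screen_lr(x, sim$identity, n_perm = n_perm,
                    seed = derive_seed(seed, 43L * s))
    targets <- intersect(sim_gene_ids(n_targets), rownames(sm$scores))
    top <- vapply(targets, function(t) {
      ord <- order(sm$pval[t, ], -abs(sm$scores[t, ]))
      match(t, colnames(sm$pval)[ord]) <= top_n
    }, logical(1))
    tibble::tibble(seed = s, moi = moi, fraction_top10 = mean(top))
  })
}

#' Deconvolution of partially confounded perturbations
#'
#' Two targets co-occur in most cells but each also appears alone in a
#' small fraction; each carries a distinct own-gene effect (one down, one
#' up). The regression engine can use the unconfounded cells to separate
#' the two effects; the rank engine, fed the overlapping cell sets, calls
#' both targets on the downregulated gene — the expected failure mode of a
#' single-marker rank test at high MOI.
#'
#' @param n_seeds replicates.
#' @param n_shared cells carrying both targets.
#' @param n_unique cells carrying each target alone.
#' @param n_ntc non-targeting control cells.
#' @param n_genes gene-axis size.
#' @param down_mult,up_mult the two distinct effects (on G001 and G002).
#' @param n_perm,fdr test settings.
#' @param seed base seed.
#' @return Tibble (seed, lr_recovered, rra_conflated).
#' @export
evaluate_deconvolution <- function(n_seeds = 10, n_shared = 160,
                                   n_unique = 20, n_ntc = 100, n_genes = 30,
                                   down_mult = 0.1, up_mult = 6,
                                   n_perm = 2000, fdr = 0.05, seed = 1) {
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    n_cells <- n_shared + 2 * n_unique + n_ntc
    cells <- sprintf("cell_%04d", seq_len(n_cells))
    genes <- sim_gene_ids(n_genes)
    has_t1 <- seq_len(n_shared + n_unique)
    has_t2 <- c(seq_len(n_shared), n_shared + n_unique + seq_len(n_unique))
    identity <- cell_identity(tibble::tibble(
      cell = c(cells[has_t1], cells[has_t2],
               cells[(n_shared + 2 * n_unique + 1):n_cells]),
      sgrna = c(paste0("G001_sg", rep(1:2, length.out = length(has_t1))),
                paste0("G002_sg", rep(1:2, length.out = length(has_t2))),
                rep("NTC_sg1", n_ntc)),
      target = rep(c("G001", "G002", "NTC"),
                   c(length(has_t1), length(has_t2), n_ntc))))
    base <- rep(2, n_genes)
    base[1:2] <- 10                     # the two effect genes, well expressed
    mu <- outer(rep(1, n_cells), base)
    dimnames(mu) <- list(cells, genes)
    mu[cells[has_t1], "G001"] <- mu[cells[has_t1], "G001"] * down_mult
    mu[cells[has_t2], "G002"] <- mu[cells[has_t2], "G002"] * up_mult
    raw <- simulate_counts(mu, nb_dispersion = 10,
                           seed = derive_seed(seed, 71L * s))
    x <- normalize_and_scale(raw)
    sm <- screen_lr(x, identity, n_perm = n_perm,
                    seed = derive_seed(seed, 73L * s), ntc_mode = "center")
    lr_ok <- sm$scores["G001", "G001"] < 0 &&
      sm$fdr_gene["G001", "G001"] < fdr &&
      sm$scores["G002", "G002"] > 0 &&
      sm$fdr_gene["G002", "G002"] < fdr &&
      sm$fdr_gene["G002", "G001"] > fdr  # the confounder is NOT blamed
    rra <- suppressWarnings(rra_test(x, identity, "G001", n_perm = n_perm,
                                     seed = derive_seed(seed, 79L * s)))
    conflated <- rra$fdr_neg[rra$target == "G002"] < fdr
    tibble::tibble(seed = s, lr_recovered = lr_ok, rra_conflated = conflated)
  })
}

#' Rank engine versus cluster-enrichment baseline
#'
#' Simulates screens where each of `n_targets` targets downregulates only
#' its own gene — a perturbation signal far too weak to reorganize global
#' clustering — and contrasts how many targets each analysis flags: the
#' rank test on each target's own gene, against chi-squared enrichment of
#' target cells in k-means expression clusters.
#'
#' @param n_seeds replicates.
#' @param n_targets,n_genes,cells_per_target screen dimensions.
#' @param multiplier implanted own-gene effect.
#' @param n_clusters k for the k-means labels supplied to the baseline.
#' @param n_perm permutations for the rank test.
#' @param fdr flagging cutoff (both analyses).
#' @param seed base seed.
#' @return Tibble (seed, rra_flagged, baseline_flagged).
#' @export
evaluate_baseline_contrast <- function(n_seeds = 10, n_targets = 20,
                                       n_genes = 50, cells_per_target = 50,
                                       multiplier = 0.3, n_clusters = 8,
                                       n_perm = 500, fdr = 0.25, seed = 1) {
  ntc_frac <- 0.1
  n_cells <- ceiling(cells_per_target * n_targets / (1 - ntc_frac))
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                      n_targets = n_targets,
                      effects = own_gene_effects(n_targets, multiplier),
                      ntc_frac = ntc_frac, seed = derive_seed(seed, 83L * s))
    sim <- simulate_screen(cfg)
    x <- normalize_and_scale(sim$raw)
    targets <- sim_gene_ids(n_targets)
    rra_flagged <- sum(vapply(targets, function(t) {
      res <- suppressWarnings(rra_test(x, sim$identity, t, n_perm = n_perm,
                                       seed = derive_seed(seed, 89L * s)))
      row <- res[res$target == t, ]
      nrow(row) == 1 && row$fdr_neg < fdr && row$score < 0
    }, logical(1)))
    labels <- withr::with_seed(derive_seed(seed, 97L * s), {
      km <- stats::kmeans(scaled_values(x), centers = n_clusters,
                          nstart = 2, iter.max = 30)
      tibble::tibble(cell = x$cell_ids,
                     cluster = paste0("k", km$cluster))
    })
    enr <- cluster_enrichment(labels, sim$identity, min_frac = 0.20,
                              fdr_cutoff = fdr)
    baseline_flagged <- length(unique(enr$target[enr$enriched]))
    tibble::tibble(seed = s, rra_flagged = rra_flagged,
                   baseline_flagged = baseline_flagged)
  })
}
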