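# Screen simulator: negative-binomial UMI counts with an extra dropout
# layer, zero-truncated Poisson MOI, expression-dependent detectability and
# marker-linked perturbation effects with known ground truth. The emitted
# files are exactly the formats the readers consume, so fixtures double as
# format tests.

#' Simulation configuration
#'
#' Defines the generative conditions of a synthetic screen. Targets are the
#' first `n_targets` genes of the axis (so own-gene effects are always
#' resolvable); each target owns three sgRNAs. Per cell, the number of
#' perturbations follows a zero-truncated Poisson; an efficiency Bernoulli
#' per (cell, target) decides whether that target's configured effects
#' apply; gene means are baseline x depth factor x applicable multipliers;
#' counts are negative binomial, with additional dropout zeros whose
#' probability is logistic in `-log(mean)`.
#'
#' @param n_cells,n_genes,n_targets screen dimensions.
#' @param moi_mean mean of the (untruncated) Poisson MOI.
#' @param nb_dispersion negative-binomial size parameter.
#' @param baseline_mean expected UMI per gene per cell (scalar or length
#'   `n_genes`).
#' @param target_gene_mean optional baseline override for the target genes
#'   (used by expression-level power sweeps).
#' @param dropout_logit_slope,dropout_logit_intercept dropout layer:
#'   `P(extra zero) = plogis(intercept - slope * log(mean))`; set the
#'   intercept to `-Inf` to disable dropout.
#' @param depth_shape shape (= rate) of the Gamma per-cell depth factor,
#'   mean 1; `Inf` fixes every cell's depth at 1.
#' @param effects tibble (target, gene, multiplier > 0) of implanted
#'   effects; `NULL` for an effects-null screen.
#' @param knockout_efficiency probability that a carried perturbation is
#'   functional in a given cell.
#' @param ntc_frac fraction of cells carrying only a non-targeting control.
#' @param seed integer seed; generation is reproducible per seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1000, n_genes = 100, n_targets = 20,
                       moi_mean = 1, nb_dispersion = 10, baseline_mean = 2,
                       target_gene_mean = NULL, depth_shape = 10,
                       dropout_logit_slope = 1,
                       dropout_logit_intercept = -1, effects = NULL,
                       knockout_efficiency = 0.8, ntc_frac = 0.1, seed = 1) {
  cfg <- list(n_cells = n_cells, n_genes = n_genes, n_targets = n_targets,
              moi_mean = moi_mean, nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean,
              target_gene_mean = target_gene_mean,
              depth_shape = depth_shape,
              dropout_logit_slope = dropout_logit_slope,
              dropout_logit_intercept = dropout_logit_intercept,
              effects = effects, knockout_efficiency = knockout_efficiency,
              ntc_frac = ntc_frac, seed = seed)
  stopifnot(n_cells >= 1, n_genes >= 1, n_targets >= 1, moi_mean > 0,
            nb_dispersion > 0, all(baseline_mean > 0),
            knockout_efficiency >= 0, knockout_efficiency <= 1,
            ntc_frac >= 0, ntc_frac <= 1)
  if (n_targets > n_genes) {
    stop("n_targets exceeds n_genes: own-gene effects unresolvable",
         call. = FALSE)
  }
  genes <- sim_gene_ids(n_genes)
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    stopifnot(all(c("target", "gene", "multiplier") %in% names(effects)))
    if (any(effects$multiplier < 0)) {
      stop("effect multipliers must be non-negative", call. = FALSE)
    }
    if (!all(effects$target %in% genes[seq_len(n_targets)])) {
      stop("effect targets must be among the first n_targets genes",
           call. = FALSE)
    }
    if (!all(effects$gene %in% genes)) {
      stop("effect genes must lie on the gene axis", call. = FALSE)
    }
    cfg$effects <- effects
  }
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%03d", seq_len(n))

#' Own-gene effect table
#'
#' Convenience builder: each of the first `n_targets` genes downregulates
#' (or upregulates) only itself by `multiplier`.
#'
#' @param n_targets number of targets.
#' @param multiplier multiplicative effect on the target's own expression.
#' @return Tibble (target, gene, multiplier).
#' @export
own_gene_effects <- function(n_targets, multiplier = 0.3) {
  g <- sim_gene_ids(n_targets)
  tibble::tibble(target = g, gene = g, multiplier = multiplier)
}

# zero-truncated Poisson via inverse CDF
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Sample counts from mean matrix
#'
#' Lower-level generator shared by [simulate_screen()] and custom designs:
#' negative-binomial counts around a given cells x genes mean matrix, with
#' the logistic dropout layer applied on top.
#'
#' @param mu cells x genes matrix of expected counts (with dimnames).
#' @param nb_dispersion negative-binomial size.
#' @param dropout_logit_slope,dropout_logit_intercept dropout layer, as in
#'   [sim_config()].
#' @param seed integer seed.
#' @return A [screen_matrix] with layer `raw_counts`.
#' @export
simulate_counts <- function(mu, nb_dispersion = 10, dropout_logit_slope = 1,
                            dropout_logit_intercept = -1, seed = 1) {
  withr::with_seed(derive_seed(seed, 1L), {
    counts <- matrix(stats::rnbinom(length(mu), size = nb_dispersion,
                                    mu = as.numeric(mu)),
                     nrow = nrow(mu))
    if (is.finite(dropout_logit_intercept)) {
      pdrop <- stats::plogis(dropout_logit_intercept -
                               dropout_logit_slope * log(pmax(mu, 1e-8)))
      counts[stats::runif(length(mu)) < pdrop] <- 0L
    }
    screen_matrix(counts, rownames(mu), colnames(mu), layer = "raw_counts")
  })
}

#' Simulate a single-cell CRISPR screen
#'
#' @param cfg a [sim_config()].
#' @return List of class `sim_screen` with `raw` (a [screen_matrix] of UMI
#'   counts), `identity` (a [cell_identity]; NTC label `"NTC"`), `truth`
#'   (tibble of the effects actually applied per cell after the efficiency
#'   draws: cell, target, gene, multiplier) and `cfg`.
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_ids(cfg$n_genes)
  targets <- genes[seq_len(cfg$n_targets)]
  cells <- sprintf("cell_%05d", seq_len(cfg$n_cells))

  withr::with_seed(derive_seed(cfg$seed, 0L), {
    base <- rep_len(cfg$baseline_mean, cfg$n_genes)
    if (!is.null(cfg$target_gene_mean)) {
      base[seq_len(cfg$n_targets)] <- cfg$target_gene_mean
    }
    is_ntc <- stats::runif(cfg$n_cells) < cfg$ntc_frac
    moi <- rztpois(cfg$n_cells, cfg$moi_mean)
    moi <- pmin(moi, cfg$n_targets)

    assign_list <- vector("list", cfg$n_cells)
    for (i in seq_len(cfg$n_cells)) {
      if (is_ntc[i]) {
        assign_list[[i]] <- tibble::tibble(
          cell = cells[i],
          sgrna = paste0("NTC_sg", sample.int(3, 1)),
          target = "NTC")
      } else {
        tg <- sample(targets, moi[i])
        assign_list[[i]] <- tibble::tibble(
          cell = cells[i],
          sgrna = paste0(tg, "_sg", sample.int(3, length(tg),
                                               replace = TRUE)),
          target = tg)
      }
    }
    assignments <- dplyr::bind_rows(assign_list)
    targeting <- assignments[assignments$target != "NTC", , drop = FALSE]
    active <- stats::runif(nrow(targeting)) < cfg$knockout_efficiency

    depth <- if (is.finite(cfg$depth_shape)) {
      stats::rgamma(cfg$n_cells, shape = cfg$depth_shape,
                    rate = cfg$depth_shape)
    } else {
      rep(1, cfg$n_cells)
    }
    mu <- outer(depth, base)
    dimnames(mu) <- list(cells, genes)

    truth <- tibble::tibble(cell = character(), target = character(),
                            gene = character(), multiplier = numeric())
    if (!is.null(cfg$effects) && any(active)) {
      act <- targeting[active, , drop = FALSE]
      truth <- dplyr::inner_join(
        act[, c("cell", "target")], cfg$effects, by = "target",
        relationship = "many-to-many")
      if (nrow(truth)) {
        ij <- cbind(match(truth$cell, cells), match(truth$gene, genes))
        # accumulate multiplicatively (a cell can carry several effects)
        for (r in seq_len(nrow(truth))) {
          mu[ij[r, 1], ij[r, 2]] <- mu[ij[r, 1], ij[r, 2]] *
            truth$multiplier[r]
        }
      }
    }
  })
  raw <- simulate_counts(mu, cfg$nb_dispersion, cfg$dropout_logit_slope,
                         cfg$dropout_logit_intercept, seed = cfg$seed)
  structure(list(raw = raw,
                 identity = cell_identity(assignments, ntc_label = "NTC"),
                 truth = truth, cfg = cfg),
            class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  cat("<sim_screen> ", x$cfg$n_cells, " cells x ", x$cfg$n_genes,
      " genes; ", x$cfg$n_targets, " targets; ",
      nrow(x$truth), " applied effect instances\n", sep = "")
  invisible(x)
}

#' Write a simulated screen to disk
#'
#' Emits the 10x-style triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`), the identity TSV and the ground-truth TSV into a
#' directory.
#'
#' @param sim a [simulate_screen()] result.
#' @param dir output directory (created if missing).
#' @export
write_screen <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::t(raw_counts(sim$raw))        # genes x cells, 10x dialect
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(paste(sim$raw$gene_ids, sim$raw$gene_ids, sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(sim$raw$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(as.data.frame(sim$identity),
                     file.path(dir, "identity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
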