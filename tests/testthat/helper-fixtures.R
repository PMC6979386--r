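# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except what a test writes itself.

`%||%` <- function(x, y) if (is.null(x)) y else x

# tiny deterministic count matrix with named axes
toy_counts <- function(values, cells = NULL, genes = NULL) {
  m <- matrix(values$x, nrow = values$nrow, byrow = TRUE)
  cells <- cells %||% paste0("c", seq_len(nrow(m)))
  genes <- genes %||% paste0("g", seq_len(ncol(m)))
  screen_matrix(m, cells, genes, layer = "raw_counts")
}

# small screen with scaled layer, for engine tests
small_screen <- function(seed = 1, n_cells = 300, n_genes = 40,
                         n_targets = 4, effects = NULL, moi_mean = 1,
                         ntc_frac = 0.2, baseline_mean = 2,
                         knockout_efficiency = 0.8) {
  cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                    n_targets = n_targets, effects = effects,
                    moi_mean = moi_mean, ntc_frac = ntc_frac,
                    baseline_mean = baseline_mean,
                    knockout_efficiency = knockout_efficiency, seed = seed)
  sim <- simulate_screen(cfg)
  sim$scaled <- normalize_and_scale(sim$raw)
  sim
}

# identity tibble literal
make_identity <- function(...) {
  rows <- list(...)
  cell_identity(tibble::tibble(
    cell = vapply(rows, `[[`, "", 1),
    sgrna = vapply(rows, `[[`, "", 2),
    target = vapply(rows, `[[`, "", 3)))
}

# reorder/subset cells of a screen_matrix (exercises the internal helper)
subset_perm <- function(x, perm) screenlink:::subset_cells(x, perm)

# closed-form binomial-tail oracle for the beta order statistic:
# P(Binom(n, u) >= k)
binom_tail_oracle <- function(u, k, n) {
  stats::pbinom(k - 1, n, u, lower.tail = FALSE)
}

# independent enumeration oracle for the rank test: exact distribution of
# rho over all n-subsets of M ranked cells, using the binomial-tail form
# and literal truncation bookkeeping (no shared code with the engine)
enumerate_rho <- function(M, n, zero_cells, side) {
  subsets <- utils::combn(M, n)
  apply(subsets, 2, function(cells_desc) {
    # cells are identified by their descending rank position; ascending
    # rank is M + 1 - r for the same cell
    if (side == "positive") {
      r <- sort(cells_desc)
      nz <- sum(!(cells_desc %in% zero_cells))
      if (nz == 0) return(1)
      min(vapply(seq_len(nz), function(k)
        binom_tail_oracle(r[k] / M, k, n), numeric(1)))
    } else {
      r <- sort(M + 1 - cells_desc)
      z <- sum(cells_desc %in% zero_cells)
      if (z == n) return(1)
      min(vapply((z + 1):n, function(k)
        binom_tail_oracle(r[k] / M, k, n), numeric(1)))
    }
  })
}

# construct a screen_matrix whose descending marker ranking is exactly the
# given order, with the listed cells having raw count zero for the marker
ranked_fixture <- function(M, zero_cells = integer(0)) {
  # marker expression M..1 over cells c01..cM; zero cells forced to 0
  counts <- matrix(0L, nrow = M, ncol = 2)
  counts[, 1] <- rev(seq_len(M))
  counts[zero_cells, 1] <- 0L
  counts[, 2] <- 5L  # constant second gene keeps totals positive
  cells <- sprintf("c%02d", seq_len(M))
  x <- screen_matrix(counts, cells, c("marker", "other"),
                     layer = "raw_counts")
  normalize_and_scale(x)
}
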