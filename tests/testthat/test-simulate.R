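# Synthetic screen generator: determinism, degenerate settings, MOI
# structure, count distribution and file round-trips

test_that("simulation is reproducible per seed and differs across seeds", {
  cfg <- sim_config(n_cells = 80, n_genes = 20, n_targets = 4, seed = 5)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(as.matrix(raw_counts(a$raw)), as.matrix(raw_counts(b$raw)))
  expect_identical(tibble::as_tibble(a$identity),
                   tibble::as_tibble(b$identity))
  cfg2 <- sim_config(n_cells = 80, n_genes = 20, n_targets = 4, seed = 6)
  c_ <- simulate_screen(cfg2)
  expect_false(identical(as.matrix(raw_counts(a$raw)),
                         as.matrix(raw_counts(c_$raw))))
})

test_that("degenerate effect settings behave as constructed", {
  # multiplier 0 with efficiency 1: target cells always at zero count
  cfg <- sim_config(n_cells = 100, n_genes = 10, n_targets = 2,
                    effects = own_gene_effects(1, 0),
                    knockout_efficiency = 1, ntc_frac = 0, seed = 2)
  sim <- simulate_screen(cfg)
  carriers <- unique(sim$identity$cell[sim$identity$target == "G001"])
  expect_true(all(raw_counts(sim$raw)[carriers, "G001"] == 0))

  # unit multipliers are an effects-null screen: truth is applied but inert
  cfg1 <- sim_config(n_cells = 60, n_genes = 10, n_targets = 2,
                     effects = own_gene_effects(2, 1), seed = 3)
  sim1 <- simulate_screen(cfg1)
  expect_true(all(sim1$truth$multiplier == 1))

  expect_error(sim_config(n_targets = 30, n_genes = 20), "exceeds")
  expect_error(sim_config(effects = tibble::tibble(
    target = "G099", gene = "G001", multiplier = 0.5)), "first n_targets")
})

test_that("applied truth is a subset of configured effects", {
  cfg <- sim_config(n_cells = 200, n_genes = 20, n_targets = 5,
                    effects = own_gene_effects(5, 0.3),
                    knockout_efficiency = 0.5, seed = 9)
  sim <- simulate_screen(cfg)
  expect_true(all(sim$truth$target == sim$truth$gene))
  expect_true(all(sim$truth$multiplier == 0.3))
  # every truth row corresponds to a carried assignment
  carried <- paste(sim$identity$cell, sim$identity$target)
  expect_true(all(paste(sim$truth$cell, sim$truth$target) %in% carried))
  # efficiency 0.5 leaves a strict subset
  expect_lt(nrow(sim$truth),
            sum(sim$identity$target != "NTC"))
})

test_that("MOI follows the zero-truncated Poisson regime", {
  for (lambda in c(1, 4)) {
    cfg <- sim_config(n_cells = 10000, n_genes = 30, n_targets = 25,
                      moi_mean = lambda, ntc_frac = 0, seed = 11)
    sim <- simulate_screen(cfg)
    moi <- table(sim$identity$cell)
    expected <- lambda / (1 - exp(-lambda))  # zero-truncation correction
    expect_lt(abs(mean(moi) - expected) / expected, 0.05)
  }
})

test_that("counts approach Poisson as dispersion grows", {
  cfg <- sim_config(n_cells = 3000, n_genes = 10, n_targets = 2,
                    baseline_mean = 8, nb_dispersion = 1e6,
                    depth_shape = Inf, dropout_logit_intercept = -Inf,
                    ntc_frac = 0, seed = 13)
  sim <- simulate_screen(cfg)
  m <- as.matrix(raw_counts(sim$raw))
  ratio <- apply(m, 2, function(v) stats::var(v) / mean(v))
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("emitted files round-trip through the readers", {
  cfg <- sim_config(n_cells = 40, n_genes = 15, n_targets = 3,
                    effects = own_gene_effects(3, 0.5), seed = 17)
  sim <- simulate_screen(cfg)
  dir <- withr::local_tempdir()
  write_screen(sim, dir)
  x <- read_expression_matrix(dir, format = "mtx_triplet")
  expect_identical(as.matrix(raw_counts(x)), as.matrix(raw_counts(sim$raw)))
  id <- read_cell_identity(file.path(dir, "identity.tsv"))
  expect_equal(tibble::as_tibble(id)[order(id$cell, id$sgrna), ],
               tibble::as_tibble(sim$identity)[order(sim$identity$cell,
                                                     sim$identity$sgrna), ])
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t")
  expect_equal(nrow(truth), nrow(sim$truth))
})

test_that("power_sweep reports null detection near zero", {
  cfg <- sim_config(n_cells = 150, n_genes = 20, n_targets = 3,
                    effects = own_gene_effects(3, 1), seed = 19)
  sweep <- power_sweep(cfg, axis = "target_expression", levels = c(2, 8),
                       n_reps = 2, engine = "rra", n_perm = 200)
  expect_equal(nrow(sweep), 4)
  expect_true(all(sweep$fraction_detected <= 1 / 3))
  expect_error(power_sweep(cfg, axis = "moi", levels = c(4, 1, 2),
                           n_reps = 1), "monotone")
})
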