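# Ridge-regression engine: design matrix, closed-form solve, permutation
# test and marker queries

test_that("design matrix encodes assignments, MOI and the NTC column", {
  id <- make_identity(list("c1", "s1", "GENEA"),
                      list("c2", "s2", "GENEA"), list("c2", "s3", "GENEB"),
                      list("c3", "n1", "NTC"))
  D <- build_design_matrix(id, c("c1", "c2", "c3"))
  expect_equal(colnames(D), c("GENEA", "GENEB", "NTC"))
  expect_equal(unname(as.matrix(D)),
               rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 1)))
  # no NTC column: control rows vanish from the design
  D2 <- build_design_matrix(id, c("c1", "c2", "c3"),
                            include_ntc_column = FALSE)
  expect_equal(colnames(D2), c("GENEA", "GENEB"))
  expect_equal(unname(as.matrix(D2["c3", , drop = FALSE])), cbind(0, 0))
  # unassigned cells are excluded with a message
  expect_message(D3 <- build_design_matrix(id, c("c1", "c2", "c3", "c9")),
                 "1 cell")
  expect_equal(nrow(D3), 3)
})

test_that("ridge_solve matches its closed forms", {
  set.seed(42)
  Y <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("c", 1:4),
                                               paste0("g", 1:3)))
  D <- diag(4)
  dimnames(D) <- list(paste0("c", 1:4), paste0("t", 1:4))
  expect_equal(unname(ridge_solve(D, Y, lambda = 0)), unname(Y),
               tolerance = 1e-12)
  expect_equal(unname(ridge_solve(D, Y, lambda = 1)), unname(Y) / 2,
               tolerance = 1e-12)

  # random systems against an independent normal-equations oracle
  for (i in 1:5) {
    D <- matrix(rbinom(6 * 3, 1, 0.5), 6, 3,
                dimnames = list(paste0("c", 1:6), paste0("t", 1:3)))
    Yr <- matrix(rnorm(24), 6, 4,
                 dimnames = list(paste0("c", 1:6), paste0("g", 1:4)))
    oracle <- solve(t(D) %*% D + 0.01 * diag(3)) %*% t(D) %*% Yr
    expect_equal(unname(ridge_solve(D, Yr, 0.01)), unname(oracle),
                 tolerance = 1e-10)
  }

  # collinear design at lambda = 0 names the offending columns
  Dc <- cbind(t1 = c(1, 1, 0), t2 = c(1, 1, 0))
  rownames(Dc) <- paste0("c", 1:3)
  expect_error(ridge_solve(Dc, matrix(rnorm(6), 3, 2), lambda = 0),
               "collinear")
  expect_error(ridge_solve(Dc, matrix(rnorm(4), 2, 2)), "cells")
})

test_that("ridge shrinkage and orthogonal-design identities hold", {
  set.seed(7)
  D <- matrix(rbinom(60, 1, 0.4), 20, 3)
  Y <- matrix(rnorm(20 * 5), 20, 5)
  norms <- vapply(c(0.01, 0.1, 1, 10), function(l)
    norm(ridge_solve(D, Y, l), "F"), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))

  # D'D = cI  =>  S = D'Y / (c + lambda)
  Do <- rbind(diag(3), diag(3))          # each column hits 2 disjoint cells
  expect_equal(unname(ridge_solve(Do, Y[1:6, ], lambda = 0.5)),
               unname(t(Do) %*% Y[1:6, ] / 2.5), tolerance = 1e-12)

  # duplicating every cell leaves the least-squares solution unchanged
  # (both D'D and D'Y double; exact at lambda = 0)
  expect_equal(ridge_solve(rbind(D, D), rbind(Y, Y), 0),
               ridge_solve(D, Y, 0), tolerance = 1e-10)
})

test_that("identical reordering of cells leaves the solution unchanged", {
  sim <- small_screen(seed = 15, effects = own_gene_effects(4, 0.3))
  cells <- sim$scaled$cell_ids
  D <- build_design_matrix(sim$identity, cells)
  Y <- scaled_values(sim$scaled)[rownames(D), ]
  perm <- rev(seq_len(nrow(D)))
  expect_equal(ridge_solve(D[perm, ], Y[perm, ], 0.01),
               ridge_solve(D, Y, 0.01), tolerance = 1e-12)
})

test_that("lr_test calibrates on null data and recovers implanted effects", {
  # null: no implanted effects; entry-wise p < 0.05 at roughly 5%
  simnull <- small_screen(seed = 41, n_cells = 300, n_genes = 30)
  smnull <- screen_lr(simnull$scaled, simnull$identity, n_perm = 400,
                      seed = 2)
  frac <- mean(smnull$pval < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(smnull$pval)) +
              0.02)
  # NTC pseudo-target stays quiet on null data
  expect_lt(max(abs(smnull$scores["NTC", ])), 0.5)
  expect_true(all(smnull$fdr_gene["NTC", ] > 0.05))

  # implanted downregulation is recovered with the right sign; n_perm
  # chosen so the BH floor across 30 genes stays below 0.05
  sim <- small_screen(seed = 42, n_cells = 500, n_genes = 30,
                      effects = own_gene_effects(4, 0.3))
  sm <- screen_lr(sim$scaled, sim$identity, n_perm = 1000, seed = 3)
  expect_true(all(diag(sm$scores[paste0("G00", 1:4),
                                 paste0("G00", 1:4)]) < 0))
  expect_true(all(diag(sm$fdr_gene[paste0("G00", 1:4),
                                   paste0("G00", 1:4)]) < 0.05))
})

test_that("query_marker returns the ranked phenotype view", {
  sim <- small_screen(seed = 43, n_cells = 400, n_genes = 30,
                      effects = own_gene_effects(4, 0.3))
  sm <- screen_lr(sim$scaled, sim$identity, n_perm = 300, seed = 5)
  q <- query_marker(sm, "G002")
  expect_true(all(diff(q$score) <= 0))
  expect_equal(q$target[q$score == min(q$score)], "G002")
  expect_error(query_marker(sm, "nope"), "not in the score matrix")
  # signature pseudo-genes are queryable after appending
  sm2 <- screen_lr(sim$scaled, sim$identity, n_perm = 50, seed = 5,
                   signatures = list(SIG = c("G010", "G011")))
  expect_true("SIG" %in% colnames(sm2$scores))
  expect_equal(nrow(query_marker(sm2, "SIG")), nrow(sm2$scores))
})

test_that("the NTC centering mode reproduces the column mode's signs", {
  sim <- small_screen(seed = 44, n_cells = 400, n_genes = 30,
                      effects = own_gene_effects(4, 0.2))
  a <- suppressWarnings(screen_lr(sim$scaled, sim$identity, n_perm = 10,
                                  seed = 1, ntc_mode = "column"))
  b <- suppressWarnings(screen_lr(sim$scaled, sim$identity, n_perm = 10,
                                  seed = 1, ntc_mode = "center"))
  own <- paste0("G00", 1:4)
  expect_true(all(diag(a$scores[own, own]) < 0))
  expect_true(all(diag(b$scores[own, own]) < 0))
})
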