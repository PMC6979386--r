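# Rank-aggregation engine: beta order statistics, truncated rho, the
# permutation test and the signed selection score

test_that("beta order-statistic p-values match closed forms", {
  expect_equal(order_statistic_pvalues(0.2), 0.2)  # Beta(1,1) is uniform
  expect_equal(order_statistic_pvalues(c(0.1, 0.5)),
               c(1 - 0.9^2, 0.5^2), tolerance = 1e-12)
  expect_equal(order_statistic_pvalues(c(0, 0.3, 0.9))[1], 0)
  expect_error(order_statistic_pvalues(c(0.5, 0.1)), "sorted")
  expect_error(order_statistic_pvalues(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("order statistics agree with the binomial tail on a grid", {
  for (n in 1:5) {
    for (u1 in seq(0, 1, by = 0.1)) {
      u <- sort(pmin(1, u1 + 0.05 * (seq_len(n) - 1)))
      expect_equal(order_statistic_pvalues(u),
                   binom_tail_oracle(u, seq_len(n), n), tolerance = 1e-12)
    }
  }
})

test_that("rank_cells orders, flags dropouts and breaks ties by barcode", {
  x <- toy_counts(list(x = c(5, 1, 1, 1, 0, 1), nrow = 3),
                  cells = c("c1", "c2", "c3"))
  x <- normalize_and_scale(x)
  rk <- rank_cells(x, "g1", "descending")
  expect_equal(unname(rk$ranks), c(1L, 2L, 3L))
  expect_equal(unname(rk$zero_flags), c(FALSE, FALSE, TRUE))
  expect_equal(rk$alpha, 2 / 3)
  rk_asc <- rank_cells(x, "g1", "ascending")
  expect_equal(unname(rk_asc$ranks), c(3L, 2L, 1L))

  # all-equal expression: deterministic barcode tie order, alpha = 1
  y <- toy_counts(list(x = c(2, 1, 2, 1, 2, 1), nrow = 3),
                  cells = c("b", "a", "c"))
  y <- normalize_and_scale(y)
  rky <- rank_cells(y, "g1", "descending")
  expect_equal(rky$ranks[c("a", "b", "c")], c(a = 1L, b = 2L, c = 3L))
  expect_equal(rky$alpha, 1)

  expect_error(rank_cells(x, "g9", "descending"), "not found")
})

test_that("rho_positive matches its closed forms and enumeration oracle", {
  x <- ranked_fixture(10)
  rk <- rank_cells(x, "marker", "descending")
  r <- rho_positive(rk, c("c01", "c02"))
  expect_equal(r$rho, min(1 - 0.9^2, 0.2^2), tolerance = 1e-12)  # 0.04
  expect_equal(r$j, 2L)

  x100 <- ranked_fixture(100)
  rk100 <- rank_cells(x100, "marker", "descending")
  expect_equal(rho_positive(rk100, "c01")$rho, 0.01, tolerance = 1e-12)

  # all target cells dropped out -> no evidence
  xz <- ranked_fixture(10, zero_cells = 9:10)
  rkz <- rank_cells(xz, "marker", "descending")
  rz <- rho_positive(rkz, c("c09", "c10"))
  expect_equal(rz$rho, 1)
  expect_equal(rz$j, 0L)

  # full agreement with the independent enumeration oracle at M = 7, n = 3
  oracle <- enumerate_rho(7, 3, zero_cells = 6:7, side = "positive")
  xf <- ranked_fixture(7, zero_cells = 6:7)
  rkf <- rank_cells(xf, "marker", "descending")
  subsets <- utils::combn(7, 3)
  got <- apply(subsets, 2, function(s)
    rho_positive(rkf, sprintf("c%02d", s))$rho)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("rho_negative excludes the leading dropout block", {
  # three target cells at the bottom of expression, two with zero counts:
  # only the third order statistic remains, Beta(3,1) CDF = u^3
  x <- ranked_fixture(10, zero_cells = 9:10)
  rk <- rank_cells(x, "marker", "ascending")
  r <- rho_negative(rk, c("c08", "c09", "c10"))
  expect_equal(r$j, 2L)
  expect_equal(r$rho, 0.3^3, tolerance = 1e-12)

  expect_equal(rho_negative(rk, c("c09", "c10"))$rho, 1)  # all excluded

  x100 <- ranked_fixture(100)
  rk100 <- rank_cells(x100, "marker", "ascending")
  expect_equal(rho_negative(rk100, "c100")$rho, 0.01, tolerance = 1e-12)

  oracle <- enumerate_rho(7, 2, zero_cells = 6:7, side = "negative")
  xf <- ranked_fixture(7, zero_cells = 6:7)
  rkf <- rank_cells(xf, "marker", "ascending")
  got <- apply(utils::combn(7, 2), 2, function(s)
    rho_negative(rkf, sprintf("c%02d", s))$rho)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("single-cell rho recovers the uniform order statistic", {
  for (M in c(10, 100)) {
    x <- ranked_fixture(M)
    rk <- rank_cells(x, "marker", "descending")
    for (r in c(1, M %/% 2)) {
      expect_equal(rho_positive(rk, sprintf("c%02d", r))$rho, r / M,
                   tolerance = 1e-12)
    }
  }
})

test_that("moving a nonzero cell to a better rank never increases rho", {
  x <- ranked_fixture(12)
  rk <- rank_cells(x, "marker", "descending")
  cells <- sprintf("c%02d", 1:12)
  for (other in c(5L, 9L)) {
    rhos <- vapply(setdiff(1:12, other), function(r)
      rho_positive(rk, cells[c(r, other)])$rho, numeric(1))
    expect_true(all(diff(rhos) >= -1e-12))
  }
})

test_that("selection score follows the signed log rule", {
  expect_equal(selection_score(0.001, 0.9), log(0.001), tolerance = 1e-10)
  expect_equal(selection_score(0.001, 0.9), -6.9078, tolerance = 1e-4)
  expect_equal(selection_score(0.9, 0.001), 6.9078, tolerance = 1e-4)
  expect_equal(selection_score(0.5, 0.5), 0)
  # zeros clamp to the permutation floor
  expect_equal(selection_score(0, 0.9, floor = 1 / 1001), log(1 / 1001))
  # vectorized
  expect_equal(selection_score(c(0.01, 0.9), c(0.9, 0.01)),
               c(log(0.01), -log(0.01)))
})

test_that("rra_test is invariant to positive rescaling of the marker", {
  sim <- small_screen(seed = 5, effects = own_gene_effects(4, 0.3))
  x <- sim$scaled
  res1 <- suppressWarnings(rra_test(x, sim$identity, "G001", n_perm = 100,
                                    seed = 2))
  # multiply the marker's raw counts by 3: ranks and dropout unchanged
  raw2 <- as.matrix(raw_counts(sim$raw))
  raw2[, "G001"] <- raw2[, "G001"] * 3L
  x2 <- normalize_and_scale(screen_matrix(raw2, x$cell_ids, x$gene_ids,
                                          layer = "raw_counts"))
  res2 <- suppressWarnings(rra_test(x2, sim$identity, "G001", n_perm = 100,
                                    seed = 2))
  expect_equal(tidy(res1), tidy(res2), tolerance = 1e-12)
})

test_that("rra_test on a tiny instance matches exhaustive enumeration", {
  # M = 6 cells, one target of n = 2; compare the permutation p-value at
  # large n_perm with the exact subset enumeration
  M <- 6
  x <- ranked_fixture(M, zero_cells = 6)
  id <- make_identity(list("c01", "s1", "T1"), list("c03", "s2", "T1"),
                      list("c02", "n1", "NTC"), list("c04", "n2", "NTC"),
                      list("c05", "n3", "NTC"), list("c06", "n4", "NTC"))
  res <- rra_test(x, id, "marker", n_perm = 4000, seed = 8)
  rhos <- enumerate_rho(M, 2, zero_cells = 6, side = "positive")
  obs <- rho_positive(rank_cells(x, "marker", "descending"),
                      c("c01", "c03"))$rho
  p_exact <- mean(rhos <= obs + 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_pos[res$target == "T1"] - p_exact), 3 * se + 5e-4)
})

test_that("rra_test warns on multi-sgRNA cells and null p-values calibrate", {
  sim <- small_screen(seed = 21, moi_mean = 3, ntc_frac = 0)
  expect_warning(rra_test(sim$scaled, sim$identity, "G010", n_perm = 20,
                          seed = 1),
                 "not suitable")

  # effects-null screen: per-direction p-values roughly uniform
  simnull <- small_screen(seed = 31, n_cells = 400, n_targets = 8)
  ps <- c()
  for (marker in c("G020", "G030")) {
    res <- suppressWarnings(rra_test(simnull$scaled, simnull$identity,
                                     marker, n_perm = 200, seed = 4))
    ps <- c(ps, res$p_neg, res$p_pos)
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("signature markers rank by mean z-score with all-zero dropout", {
  sim <- small_screen(seed = 12)
  sig <- list(SIG = c("G005", "G006", "ABSENT"))
  expect_warning(rk <- rank_cells(sim$scaled, sig, "descending"), "absent")
  expect_equal(rk$marker_id, "SIG")
  raw <- as.matrix(raw_counts(sim$raw))
  both_zero <- raw[, "G005"] == 0 & raw[, "G006"] == 0
  expect_equal(unname(rk$zero_flags), unname(both_zero))
  # ranked by the mean of member z-scores
  sc <- scaled_values(sim$scaled)
  mean_z <- rowMeans(sc[, c("G005", "G006")])
  expect_equal(order(rk$ranks), order_radix(-mean_z, sim$scaled$cell_ids))
})
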