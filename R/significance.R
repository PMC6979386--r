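#' Permutation plan
#'
#' Fixes the number of permutation rounds and the seed so both statistical
#' engines can share one reproducible shuffling scheme. Each round's
#' permutation depends only on `(seed, round)`.
#'
#' @param n_perm number of permutation rounds (>= 1).
#' @param seed integer seed.
#' @return A list of class `permutation_plan` with fields `n_perm`, `seed`,
#'   `scheme` and the attainable p-value `floor` `1/(n_perm + 1)`.
#' @export
permutation_plan <- function(n_perm, seed) {
  if (!is.numeric(n_perm) || n_perm < 1) {
    stop("n_perm must be >= 1", call. = FALSE)
  }
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 scheme = "shuffle_labels", floor = 1 / (n_perm + 1)),
            class = "permutation_plan")
}

# one round's cell permutation (positions 1..n_cells)
plan_permutation <- function(plan, round, n_cells) {
  withr::with_seed(derive_seed(plan$seed, round), sample.int(n_cells))
}

#' Permute a cell identity table
#'
#' Reassigns each cell's whole sgRNA bundle to another cell, so the per-cell
#' multiplicity of infection and every target's cell count are preserved;
#' only the correspondence between expression profiles and perturbations is
#' broken. This is the null model for the permutation tests.
#'
#' @param identity a [cell_identity].
#' @param plan a [permutation_plan].
#' @param round round index in `1..n_perm`.
#' @return A permuted [cell_identity].
#' @export
permute_identity <- function(identity, plan, round) {
  stopifnot(inherits(plan, "permutation_plan"))
  if (round > plan$n_perm) stop("round exceeds n_perm", call. = FALSE)
  cells <- sort(unique(identity$cell), method = "radix")
  perm <- plan_permutation(plan, round, length(cells))
  new_cells <- cells[perm]
  out <- identity
  out$cell <- new_cells[match(identity$cell, cells)]
  out
}

#' Empirical permutation p-value
#'
#' Add-one estimator `p = (1 + #qualifying) / (1 + B)`, bounded below by
#' `1/(B + 1)` so no p-value is exactly zero.
#'
#' @param observed observed statistic.
#' @param permuted vector of B permuted statistics.
#' @param tail `"le"` (permuted <= observed counts), `"ge"`, or
#'   `"two_sided_abs"` (`|permuted| >= |observed|`).
#' @return p-value in `[1/(B+1), 1]`.
#' @export
empirical_pvalue <- function(observed, permuted,
                             tail = c("le", "ge", "two_sided_abs")) {
  tail <- match.arg(tail)
  if (!length(permuted)) stop("permuted values required", call. = FALSE)
  k <- switch(tail,
              le = sum(permuted <= observed),
              ge = sum(permuted >= observed),
              two_sided_abs = sum(abs(permuted) >= abs(observed)))
  (1 + k) / (1 + length(permuted))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control over one family of p-values
#' (delegates to [stats::p.adjust()] after validating the input range).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted q-values mapped back to the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
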