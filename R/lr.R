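# Ridge-regression engine: estimate the K x N matrix of perturbation
# effects on every gene from the binary cell-identity design matrix,
# with permutation-based significance. Handles high-MOI cells, where
# several perturbations share one expression profile.

#' Build the binary cell-identity design matrix
#'
#' `d[j, X] = 1` iff cell `j` carries an sgRNA targeting `X`. High-MOI
#' cells yield several ones per row. Non-targeting control cells get a
#' dedicated NTC pseudo-target column (the default negative-control
#' handling), which keeps the closed-form ridge solution unchanged.
#'
#' @param identity a [cell_identity].
#' @param cells ordered cell barcodes defining the row axis; cells without
#'   any assignment are dropped with a message.
#' @param include_ntc_column add the NTC pseudo-target as the last column.
#' @return Sparse binary matrix (dgCMatrix) with cell/target dimnames.
#' @export
build_design_matrix <- function(identity, cells, include_ntc_column = TRUE) {
  ntc <- ntc_label(identity)
  assigned <- unique(identity$cell)
  missing <- setdiff(cells, assigned)
  if (length(missing)) {
    message("build_design_matrix: ", length(missing),
            " cell(s) without assignments excluded")
    cells <- setdiff(cells, missing)
  }
  if (!length(cells)) stop("no assigned cells", call. = FALSE)
  df <- identity[identity$cell %in% cells, , drop = FALSE]
  targets <- sort(unique(df$target[df$target != ntc]), method = "radix")
  if (include_ntc_column && any(df$target == ntc)) {
    targets <- c(targets, ntc)
  } else {
    df <- df[df$target != ntc, , drop = FALSE]
  }
  i <- match(df$cell, cells)
  j <- match(df$target, targets)
  keep <- !is.na(j)
  D <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(length(cells), length(targets)),
                            dimnames = list(cells, targets))
  D@x[] <- 1  # collapse multi-guide duplicates to binary
  methods::as(D, "CsparseMatrix")
}

#' Closed-form ridge solve
#'
#' Solves `S = (D'D + lambda I)^{-1} D'Y` through a Cholesky factorization
#' of the K x K system (no explicit inverse). With `lambda = 0` the system
#' must be full rank; collinear design columns are reported by name.
#'
#' @param D M x K design matrix (dense or sparse).
#' @param Y M x N expression matrix (the scaled layer, or any numeric
#'   matrix with matching rows).
#' @param lambda ridge penalty (default 0.01).
#' @return K x N dense score matrix with target/gene dimnames.
#' @export
ridge_solve <- function(D, Y, lambda = 0.01) {
  if (nrow(D) != nrow(Y)) {
    stop("D and Y disagree on the number of cells (", nrow(D), " vs ",
         nrow(Y), ")", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  K <- ncol(D)
  A <- as.matrix(Matrix::crossprod(D)) + diag(lambda, K)
  if (lambda == 0) {
    qrA <- qr(A)
    if (qrA$rank < K) {
      bad <- colnames(D)[qrA$pivot[-seq_len(qrA$rank)]]
      stop("singular design at lambda = 0; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  R <- tryCatch(chol(A),
                error = function(e) chol(A + diag(1e-10, K)))  # jitter
  B <- as.matrix(Matrix::crossprod(D, Y))
  S <- backsolve(R, backsolve(R, B, transpose = TRUE))
  dimnames(S) <- list(colnames(D), colnames(Y))
  S
}

#' Ridge perturbation test
#'
#' Computes the observed score matrix `S = (D'D + lambda I)^{-1} D'Y`, then
#' a permutation null in which the correspondence between expression rows
#' and identity rows is shuffled by one global permutation per round
#' (preserving within-cell MOI structure and every column sum; `D'D` is
#' permutation-invariant so the factorization is reused). Per entry, the
#' empirical p-value is two-sided on `|s|` by default; Benjamini-Hochberg
#' adjustment is emitted for both natural families: per target row across
#' genes (a perturbation's transcriptome scan) and per gene column across
#' targets (a phenotype scan).
#'
#' @param D design matrix from [build_design_matrix()].
#' @param Y scaled expression matrix with rows matching `D`.
#' @param lambda ridge penalty (default 0.01).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail `"two_sided_abs"` (default) or one-sided `"le"`/`"ge"`.
#' @return An object of class `score_matrix`: list with `scores`, `pval`,
#'   `fdr_gene` (row families), `fdr_target` (column families), `lambda`,
#'   `n_perm`, `seed`.
#' @export
lr_test <- function(D, Y, lambda = 0.01, n_perm = 1000, seed = 1,
                    tail = c("two_sided_abs", "le", "ge")) {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (n_perm < 19) {
    warning("n_perm = ", n_perm, " limits the attainable p-value to ",
            signif(1 / (n_perm + 1), 3))
  }
  M <- nrow(D)
  K <- ncol(D)
  A <- as.matrix(Matrix::crossprod(D)) + diag(lambda, K)
  R <- tryCatch(chol(A), error = function(e) chol(A + diag(1e-10, K)))
  solve_S <- function(B) backsolve(R, backsolve(R, B, transpose = TRUE))
  Y <- as.matrix(Y)
  S <- solve_S(as.matrix(Matrix::crossprod(D, Y)))
  dimnames(S) <- list(colnames(D), colnames(Y))
  cnt <- matrix(0, K, ncol(Y))
  cmp <- switch(tail,
                two_sided_abs = function(Sp) abs(Sp) >= abs(S),
                le = function(Sp) Sp <= S,
                ge = function(Sp) Sp >= S)
  withr::with_seed(derive_seed(seed, 0L), {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(M)
      Sp <- solve_S(as.matrix(Matrix::crossprod(D, Y[perm, , drop = FALSE])))
      cnt <- cnt + cmp(Sp)
    }
  })
  pval <- (1 + cnt) / (1 + n_perm)
  fdr_gene <- t(apply(pval, 1, benjamini_hochberg))
  fdr_target <- apply(pval, 2, benjamini_hochberg)
  if (is.null(dim(fdr_target))) fdr_target <- matrix(fdr_target, nrow = K)
  dimnames(pval) <- dimnames(S)
  dimnames(fdr_gene) <- dimnames(S)
  dimnames(fdr_target) <- dimnames(S)
  structure(list(scores = S, pval = pval, fdr_gene = fdr_gene,
                 fdr_target = fdr_target, lambda = lambda,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 tail = tail),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", nrow(x$scores), " targets x ", ncol(x$scores),
      " genes (lambda = ", x$lambda, ", n_perm = ", x$n_perm, ")\n", sep = "")
  invisible(x)
}

#' Rank perturbations by their effect on one marker
#'
#' Extracts one gene column of a [lr_test()] result as a ranked table: the
#' phenotype-scan view, with FDR adjusted across targets within that
#' marker. Ties in score are broken by target id for a stable order.
#'
#' @param sm a `score_matrix`.
#' @param marker gene id (or appended signature pseudo-gene) to query.
#' @return Tibble (target, score, p, fdr), sorted by decreasing score.
#' @export
query_marker <- function(sm, marker) {
  stopifnot(inherits(sm, "score_matrix"))
  if (!marker %in% colnames(sm$scores)) {
    stop("marker '", marker, "' not in the score matrix", call. = FALSE)
  }
  out <- tibble::tibble(target = rownames(sm$scores),
                        score = sm$scores[, marker],
                        p = sm$pval[, marker],
                        fdr = sm$fdr_target[, marker])
  out[order_radix(-out$score, out$target), ]
}

#' Run the regression engine on a screen
#'
#' Pipeline convenience: builds the design matrix over the cells shared by
#' the expression matrix and the identity table, optionally appends
#' per-cell gene-signature scores to the response as pseudo-genes, and runs
#' [lr_test()]. The alternative negative-control mode centers every gene of
#' the response at its mean over NTC-only cells instead of adding an NTC
#' column.
#'
#' @param x a [screen_matrix] with a scaled layer.
#' @param identity a [cell_identity].
#' @param lambda,n_perm,seed passed to [lr_test()].
#' @param signatures optional named list of gene vectors appended to the
#'   response as signature pseudo-genes.
#' @param ntc_mode `"column"` (default: NTC pseudo-target column) or
#'   `"center"` (subtract NTC-cell gene means; NTC cells keep all-zero
#'   design rows).
#' @return A `score_matrix`.
#' @export
screen_lr <- function(x, identity, lambda = 0.01, n_perm = 1000, seed = 1,
                      signatures = NULL, ntc_mode = c("column", "center")) {
  ntc_mode <- match.arg(ntc_mode)
  cells <- intersect(x$cell_ids, unique(identity$cell))
  if (!length(cells)) stop("no cells shared by matrix and identity",
                           call. = FALSE)
  keep <- match(cells, x$cell_ids)
  Y <- scaled_values(x)[keep, , drop = FALSE]
  if (!is.null(signatures)) {
    for (nm in names(signatures)) {
      present <- intersect(signatures[[nm]], x$gene_ids)
      if (!length(present)) next
      Y <- cbind(Y, rowMeans(Y[, present, drop = FALSE]))
      colnames(Y)[ncol(Y)] <- nm
    }
  }
  if (ntc_mode == "center") {
    ntc <- ntc_label(identity)
    smry <- identity_summary(identity)
    ntc_cells <- intersect(smry$cell[smry$ntc_only], cells)
    if (length(ntc_cells)) {
      Y <- sweep(Y, 2, colMeans(Y[ntc_cells, , drop = FALSE]), `-`)
    }
    D <- build_design_matrix(identity, cells, include_ntc_column = FALSE)
    # NTC-only cells keep all-zero rows in this mode
    zero_rows <- setdiff(cells, rownames(D))
    if (length(zero_rows)) {
      Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(zero_rows), ncol(D)),
                                dimnames = list(zero_rows, colnames(D)))
      D <- rbind(D, Z)[cells, , drop = FALSE]
    }
  } else {
    D <- build_design_matrix(identity, cells, include_ntc_column = TRUE)
    Y <- Y[rownames(D), , drop = FALSE]
  }
  lr_test(D, Y[rownames(D), , drop = FALSE], lambda = lambda,
          n_perm = n_perm, seed = seed)
}

#' Write a score matrix to delimited files
#'
#' Emits `<prefix>_scores.tsv`, `<prefix>_pvals.tsv`, `<prefix>_fdr.tsv`
#' (gene-family FDR) with shared headers, plus a long-format
#' `<prefix>_long.tsv` (target, gene, score, p, fdr).
#'
#' @param sm a `score_matrix`.
#' @param prefix output path prefix.
#' @export
write_score_matrix <- function(sm, prefix) {
  hdr <- sprintf("# screenlink %s lr: lambda=%g n_perm=%d seed=%d",
                 as.character(utils::packageVersion("screenlink")),
                 sm$lambda, sm$n_perm, sm$seed)
  emit <- function(m, path) {
    writeLines(hdr, path)
    df <- data.frame(target = rownames(m), m, check.names = FALSE)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  emit(sm$scores, paste0(prefix, "_scores.tsv"))
  emit(sm$pval, paste0(prefix, "_pvals.tsv"))
  emit(sm$fdr_gene, paste0(prefix, "_fdr.tsv"))
  long <- tidy(sm)
  path <- paste0(prefix, "_long.tsv")
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(as.data.frame(long), path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(prefix)
}
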