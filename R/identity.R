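#' Cell identity table
#'
#' The cell identity maps each cell barcode to the sgRNAs it carries and
#' their target genes or elements. Cells may carry several sgRNAs (high
#' multiplicity of infection); non-targeting controls are marked by a
#' dedicated target label.
#'
#' @param assignments data frame with columns `cell`, `sgrna`, `target`.
#' @param ntc_label target label denoting non-targeting controls.
#' @return A tibble of class `cell_identity` with attribute `ntc_label`.
#' @export
cell_identity <- function(assignments, ntc_label = "NTC") {
  df <- tibble::as_tibble(assignments)
  stopifnot(all(c("cell", "sgrna", "target") %in% names(df)))
  df <- dplyr::mutate(df, dplyr::across(c("cell", "sgrna", "target"),
                                        as.character))
  if (nrow(df) == 0) stop("identity table is empty", call. = FALSE)
  # an sgRNA must map to exactly one target
  map <- dplyr::distinct(df, .data$sgrna, .data$target)
  bad <- map$sgrna[duplicated(map$sgrna)]
  if (length(bad)) {
    stop("sgRNA '", bad[[1]], "' is mapped to multiple targets",
         call. = FALSE)
  }
  df <- dplyr::distinct(df, .data$cell, .data$sgrna, .keep_all = TRUE)
  structure(df, class = c("cell_identity", class(tibble::tibble())),
            ntc_label = ntc_label)
}

#' Read a cell identity table
#'
#' Delimited text with columns (cell, sgrna, target); a header row is
#' detected and skipped.
#'
#' @param path delimited file (tab or comma separated; gzip accepted).
#' @param ntc_label target label for non-targeting controls.
#' @return A [cell_identity] tibble.
#' @export
read_cell_identity <- function(path, ntc_label = "NTC") {
  first <- readLines(open_maybe_gz(path), n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("^(cell|barcode)", tolower(first))
  tab <- utils::read.table(open_maybe_gz(path), sep = sep, header = header,
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("cell", "sgrna", "target")
  cell_identity(tab, ntc_label = ntc_label)
}

ntc_label <- function(identity) attr(identity, "ntc_label") %||% "NTC"

#' Per-cell assignment summary
#'
#' @param identity a [cell_identity].
#' @return Tibble with one row per cell: `cell`, `moi` (number of sgRNAs),
#'   `targets` (list column), `ntc_only` (carries only non-targeting
#'   controls).
#' @export
identity_summary <- function(identity) {
  ntc <- ntc_label(identity)
  identity |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(moi = dplyr::n(),
                     targets = list(unique(.data$target)),
                     ntc_only = all(.data$target == ntc),
                     .groups = "drop")
}

# cell sets per (non-control) target, as positions in `cells`
target_cell_sets <- function(identity, cells, include_ntc = FALSE) {
  ntc <- ntc_label(identity)
  df <- identity[identity$cell %in% cells, , drop = FALSE]
  if (!include_ntc) df <- df[df$target != ntc, , drop = FALSE]
  targets <- sort(unique(df$target), method = "radix")
  if (include_ntc && ntc %in% targets) {
    targets <- c(setdiff(targets, ntc), ntc)
  }
  pos <- match(df$cell, cells)
  lapply(stats::setNames(targets, targets), function(t) {
    sort(unique(pos[df$target == t]))
  })
}
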