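#' @importFrom rlang .data %||%
#' @importFrom methods as
#' @importFrom stats pbeta pbinom rnbinom rgamma rlnorm runif qpois dpois
#'   plogis setNames p.adjust chisq.test sd kmeans prcomp
#' @importFrom utils head
NULL

# deterministic per-round permutation seed derived from one analysis seed;
# kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, round) {
  as.integer((as.numeric(seed) %% 59999L) * 29989 + round %% 29989)
}

# radix sort: locale-independent deterministic ordering for barcodes
order_radix <- function(...) order(..., method = "radix")
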