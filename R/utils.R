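#' @importFrom rlang %||% abort warn
#' @importFrom stats pnorm p.adjust rpois rnorm runif rbinom kmeans fisher.test
#'   wilcox.test setNames sd poisson glm.fit plogis
#' @importFrom methods as is
NULL

stop_config <- function(msg) rlang::abort(msg, class = "bifurcgrn_config_error")
stop_validate <- function(msg) rlang::abort(msg, class = "bifurcgrn_validation_error")

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_config(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  as.numeric(x)
}

#' Logarithmic decay-length grid
#'
#' Candidate exponential decay lengths (bp) for regulatory-potential fitting,
#' log-spaced so that the brute-force grid search stays exact and cheap.
#'
#' @param from,to Grid endpoints in bp; defaults span 500 bp to 100 kb.
#' @param n Number of grid points.
#' @return Numeric vector of decay lengths in bp.
#' @export
decay_grid <- function(from = 500, to = 1e5, n = 12) {
  if (from <= 0 || to <= from) stop_config("decay grid endpoints must satisfy 0 < from < to")
  exp(seq(log(from), log(to), length.out = n))
}

#' Library-size normalized log expression
#'
#' log1p of counts scaled per cell to a common library size; the expression
#' input expected by [fit_state_grn()] and the knockout simulator.
#'
#' @param counts gene x cell count matrix (dense or sparse).
#' @param scale Common library size after scaling (default median of totals).
#' @return Dense gene x cell matrix of log-normalized expression.
#' @export
normalize_expression <- function(counts, scale = NULL) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1
  scale <- scale %||% stats::median(libsize)
  log1p(sweep(counts, 2, libsize, "/") * scale)
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}
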