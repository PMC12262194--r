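#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a regulatory-potential model
#'
#' One row per linked peak with its distance, side and decay weight.
#' @param x An `rp_model`.
#' @param ... Unused.
#' @return Tibble: gene, peak, distance, side, weight.
#' @export
tidy.rp_model <- function(x, ...) {
  dplyr::mutate(x$peaks[, c("peak", "distance", "side", "weight")],
                gene = x$gene, .before = 1)
}

#' One-row summary of a regulatory-potential model fit
#' @param x An `rp_model`.
#' @param ... Unused.
#' @return Tibble: gene, decay_up, decay_down, alpha, beta, loglik,
#'   loglik_null, lr (likelihood-ratio statistic), n_peaks, degenerate.
#' @export
glance.rp_model <- function(x, ...) {
  tibble::tibble(gene = x$gene, decay_up = x$decay_up, decay_down = x$decay_down,
                 alpha = x$alpha, beta = x$beta,
                 loglik = x$loglik, loglik_null = x$loglik_null,
                 lr = x$loglik - x$loglik_null,
                 n_peaks = nrow(x$peaks), degenerate = x$degenerate)
}

#' Per-cell scores of a perturbation result
#' @param x A `perturbation_result`.
#' @param ... Unused.
#' @return Tibble: cell, ps.
#' @export
tidy.perturbation_result <- function(x, ...) x$cells

#' One-row summary of a perturbation result
#' @param x A `perturbation_result`.
#' @param ... Unused.
#' @return Tibble: tf (if recorded), net_gc, net_pb, delta_ps.
#' @export
glance.perturbation_result <- function(x, ...) {
  tibble::tibble(tf = attr(x, "tf") %||% NA_character_,
                 net_gc = x$net_gc, net_pb = x$net_pb, delta_ps = x$delta_ps)
}

#' Long-format TF centralities
#' @param x A `centrality_matrix`.
#' @param ... Unused.
#' @return Tibble: tf, state, centrality, scaled.
#' @export
tidy.centrality_matrix <- function(x, ...) {
  long <- as.data.frame.table(x$centrality, responseName = "centrality",
                              stringsAsFactors = FALSE)
  names(long)[1:2] <- c("tf", "state")
  long$scaled <- as.data.frame.table(x$scaled)$Freq
  tibble::as_tibble(long)
}

#' Clonal test table as a plain tibble
#' @param x A `clonal_test`.
#' @param ... Unused.
#' @return Tibble: category, observed, sim_mean, sim_sd, z, p, degenerate.
#' @export
tidy.clonal_test <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("category", "observed", "sim_mean",
                                 "sim_sd", "z", "p", "degenerate")])
}

#' One-row summary of a clonal concordance test
#' @param x A `clonal_test`.
#' @param ... Unused.
#' @return Tibble: n_sim, mode, min_p.
#' @export
glance.clonal_test <- function(x, ...) {
  tibble::tibble(n_sim = attr(x, "n_sim"), mode = attr(x, "mode"),
                 min_p = min(x$p))
}
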