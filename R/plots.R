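#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_tile geom_col
#'   geom_point geom_errorbar scale_fill_gradient2 labs theme_minimal
#'   position_dodge arrow unit facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Arrow plot of a flow field over the embedding
#' @param object A `vector_field`.
#' @param scale Multiplier applied to the vectors for display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vector_field <- function(object, scale = 1, ...) {
  d <- object$cells
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(size = 0.3, colour = "grey70") +
    geom_segment(aes(xend = .data$x + scale * .data$vx,
                     yend = .data$y + scale * .data$vy),
                 arrow = arrow(length = unit(0.1, "cm")), linewidth = 0.2) +
    labs(title = paste(object$kind, "flow"), x = "embedding x", y = "embedding y") +
    theme_minimal()
}

#' Heatmap of scaled TF centralities across states
#' @param object A `centrality_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.centrality_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$state, y = .data$tf, fill = .data$scaled)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "cell state", y = "TF", fill = "scaled\ncentrality") +
    theme_minimal()
}

#' Observed vs simulated clonotype category counts
#' @param object A `clonal_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonal_test <- function(object, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(d[, c("category", "observed", "sim_mean")],
                              -"category", names_to = "which", values_to = "n")
  sd_map <- setNames(d$sim_sd, d$category)
  long$sd <- ifelse(long$which == "sim_mean", sd_map[long$category], NA_real_)
  ggplot(long, aes(x = .data$category, y = .data$n, fill = .data$which)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$n - .data$sd, ymax = .data$n + .data$sd),
                  position = position_dodge(width = 0.8), width = 0.2,
                  na.rm = TRUE) +
    labs(x = "clone category", y = "clonotypes", fill = NULL) +
    theme_minimal()
}

#' Bar plot of knockout delta perturbation scores per TF
#' @param results Named list of `perturbation_result` (names = TFs) or a
#'   tibble with `tf` and `delta_ps`.
#' @return A ggplot.
#' @export
plot_delta_ps <- function(results) {
  d <- if (is.data.frame(results)) tibble::as_tibble(results) else
    purrr::map_dfr(results, glance)
  ggplot(d, aes(x = stats::reorder(.data$tf, .data$delta_ps), y = .data$delta_ps,
                fill = .data$delta_ps > 0)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "net GC - net PB perturbation score") +
    theme_minimal()
}
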