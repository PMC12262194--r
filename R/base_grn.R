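#' Assemble the binary base network from in-silico deletion scores
#'
#' Retains the k = round(quantile x n_pairs) largest scores across the whole
#' TF x gene matrix (a global cut, not per-TF), then adds co-accessibility
#' fallback links — strictly above `coacc_min` and restricted to modeled
#' genes — for TFs absent from the score matrix. At the paper-scale matrix
#' (50 TFs x 4,306 genes, 5% cut) this yields ~215 links per TF on average.
#'
#' @param isd An `isd_tbl` (long) or TF x gene score matrix covering every
#'   pair.
#' @param quantile Fraction of all pairs retained (default 0.05).
#' @param coacc Optional co-accessibility link table: `tf`, `gene`, `score`.
#' @param coacc_min Strict lower bound for co-accessibility links.
#' @param modeled_genes Genes eligible for fallback links (default: the
#'   genes of the score matrix).
#' @return A `base_grn` tibble: `tf`, `gene`, `score`, `source`
#'   ("isd" or "coaccessibility").
#' @export
assemble_base_grn <- function(isd, quantile = 0.05, coacc = NULL,
                              coacc_min = 0.8, modeled_genes = NULL) {
  if (quantile <= 0 || quantile >= 1) stop_config("`quantile` must lie in (0, 1)")
  if (is.matrix(isd)) {
    isd <- tibble::as_tibble(as.data.frame.table(isd, responseName = "score",
                                                 stringsAsFactors = FALSE))
    names(isd)[1:2] <- c("tf", "gene")
  }
  if (nrow(isd) == 0) stop_config("`isd` must be non-empty")
  modeled_genes <- modeled_genes %||% unique(isd$gene)

  k <- round(quantile * nrow(isd))
  if (all(isd$score == 0)) {
    rlang::warn("all ISD scores are zero; no isd-sourced links retained")
    links <- isd[0, c("tf", "gene", "score")]
  } else {
    links <- dplyr::slice_head(
      dplyr::arrange(isd[, c("tf", "gene", "score")],
                     dplyr::desc(.data$score), .data$tf, .data$gene),
      n = k)
  }
  links$source <- rep("isd", nrow(links))

  if (!is.null(coacc) && nrow(coacc) > 0) {
    isd_tfs <- unique(isd$tf)
    fallback <- dplyr::filter(
      coacc,
      !.data$tf %in% isd_tfs,
      .data$score > coacc_min,
      .data$gene %in% modeled_genes)
    fallback <- dplyr::distinct(fallback, .data$tf, .data$gene, .keep_all = TRUE)
    if (nrow(fallback) > 0) {
      fallback$source <- "coaccessibility"
      links <- dplyr::bind_rows(links, fallback[, names(links)])
    }
  }
  attr(links, "quantile") <- quantile
  attr(links, "tfs") <- unique(c(unique(isd$tf), links$tf))
  attr(links, "genes") <- modeled_genes
  class(links) <- c("base_grn", setdiff(class(links), "isd_tbl"))
  links
}
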