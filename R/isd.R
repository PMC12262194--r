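#' In-silico deletion score of a TF for one gene
#'
#' Deletes (hard-masks) the model peaks that overlap the TF's binding
#' regions by at least 1 bp, recomputes the regulatory potential from the
#' remaining peaks with the decay lengths frozen, refits only the intercept
#' and RP coefficient, and reports the drop in Poisson log-likelihood
#' relative to the full model. The score is exactly 0 when no model peak
#' overlaps the binding set, and deleting every peak reduces to an
#' intercept-only refit.
#'
#' @param model An `rp_model` (non-degenerate for a meaningful score).
#' @param acc Peak x cell counts covering the model peaks.
#' @param expr Gene x cell count matrix or the gene's count vector.
#' @param libsize Per-cell library-size scale.
#' @param tf_peaks TF binding regions: tibble with `chrom`, `start`, `end`
#'   (0-based half-open) or a `GRanges`.
#' @return Scalar score (log-likelihood units) with attribute `n_deleted`.
#' @export
isd_score <- function(model, acc, expr, libsize, tf_peaks) {
  stopifnot(inherits(model, "rp_model"))
  if (model$degenerate) {
    return(structure(0, n_deleted = 0L, degenerate = TRUE))
  }
  hit <- overlaps_any(model$peaks, tf_peaks)
  if (!any(hit)) return(structure(0, n_deleted = 0L, degenerate = FALSE))

  y <- if (is.matrix(expr) || inherits(expr, "Matrix")) as.numeric(expr[model$gene, ]) else as.numeric(expr)
  log_lib <- log(libsize)
  kept <- model$peaks[!hit, , drop = FALSE]
  if (nrow(kept) == 0) {
    del <- fit_poisson_intercept(y, log_lib)
  } else {
    A <- as.matrix(acc[kept$peak, , drop = FALSE])
    rp <- crossprod(A, kept$weight)[, 1]
    del <- if (all(A == 0)) fit_poisson_intercept(y, log_lib) else
      fit_poisson_rp(y, rp, log_lib)
  }
  structure(model$loglik - del$loglik, n_deleted = sum(hit), degenerate = FALSE)
}

overlaps_any <- function(peaks, tf_peaks) {
  if (is.data.frame(tf_peaks)) {
    if (nrow(tf_peaks) == 0) return(rep(FALSE, nrow(peaks)))
    tf_gr <- peaks_to_granges(tf_peaks)
  } else {
    tf_gr <- tf_peaks
    if (length(tf_gr) == 0) return(rep(FALSE, nrow(peaks)))
  }
  peak_gr <- peaks_to_granges(peaks)
  suppressWarnings(
    IRanges::overlapsAny(peak_gr, tf_gr, minoverlap = 1L, ignore.strand = TRUE))
}

#' TF x gene matrix of in-silico deletion scores
#'
#' Scores every (TF, gene) pair; when a TF has several binding sets (e.g.
#' several ChIP-seq experiments), the top score per pair is retained and the
#' arg-max set recorded as provenance.
#'
#' @param models Named list of `rp_model` objects (one per gene).
#' @param tf_binding Named list: TF -> list of binding-region tables
#'   (each a tibble chrom/start/end or a GRanges).
#' @param acc,expr,libsize As in [isd_score()]; `expr` must be the
#'   gene x cell matrix.
#' @return An `isd_tbl` tibble with one row per (tf, gene): `score` and
#'   `set` (index of the retained binding set).
#' @export
isd_matrix <- function(models, tf_binding, acc, expr, libsize) {
  if (length(tf_binding) == 0) stop_validate("`tf_binding` must map at least one TF")
  if (is.null(names(tf_binding)) || any(!nzchar(names(tf_binding)))) {
    stop_validate("`tf_binding` must be a named list keyed by TF")
  }
  rows <- purrr::imap_dfr(tf_binding, function(sets, tf) {
    if (length(sets) == 0) stop_validate(sprintf("TF '%s' has no binding sets", tf))
    purrr::imap_dfr(models, function(model, gene) {
      scores <- vapply(sets, function(s)
        as.numeric(isd_score(model, acc, expr, libsize, s)), numeric(1))
      best <- which.max(scores)
      tibble::tibble(tf = tf, gene = gene, score = scores[best],
                     set = as.integer(best))
    })
  })
  class(rows) <- c("isd_tbl", class(rows))
  rows
}

#' Wide TF x gene matrix view of an `isd_tbl`
#' @param x An `isd_tbl`.
#' @param ... Unused.
#' @return Numeric matrix, TFs in rows, genes in columns.
#' @export
as.matrix.isd_tbl <- function(x, ...) {
  tfs <- unique(x$tf); genes <- unique(x$gene)
  m <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  m[cbind(x$tf, x$gene)] <- x$score
  m
}
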