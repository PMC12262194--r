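#' Link ATAC peaks to genes around their TSS
#'
#' Maps every gene to all peaks whose nearest edge lies within `window` bp of
#' the gene's TSS. Distance is measured TSS-to-nearest-peak-edge and is 0 for
#' a peak spanning the TSS; the sign is relative to the gene's strand, with
#' upstream (5' of the TSS) negative.
#'
#' @param peaks Tibble of peaks: `peak`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param tss Tibble of TSS records: `gene`, `chrom`, `pos` (0-based),
#'   `strand` ("+" or "-").
#' @param window Maximum |distance| in bp (> 0).
#' @return A `peak_gene_index` tibble: gene, peak, chrom, start, end,
#'   distance (signed bp), side ("upstream"/"downstream"), with the window
#'   stored as an attribute.
#' @export
link_peaks_to_genes <- function(peaks, tss, window = 1e5) {
  if (window <= 0) stop_config("`window` must be > 0")
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)),
            all(c("gene", "chrom", "pos", "strand") %in% names(tss)))
  if (!"peak" %in% names(peaks)) {
    peaks$peak <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  }
  missing_chr <- setdiff(unique(tss$chrom), unique(peaks$chrom))
  if (length(missing_chr) > 0) {
    rlang::warn(sprintf(
      "excluding %d TSS record(s) on chromosome(s) absent from the peak set: %s",
      sum(tss$chrom %in% missing_chr), paste(missing_chr, collapse = ", ")))
    tss <- tss[!tss$chrom %in% missing_chr, ]
  }

  peak_gr <- peaks_to_granges(peaks)
  # TSS expanded by the window; any-overlap hits are the candidate pairs
  tss_gr <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = pmax(tss$pos + 1L - window, 1L),
                              end = tss$pos + 1L + window)
  )
  hits <- GenomicRanges::findOverlaps(tss_gr, peak_gr, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits)
  pj <- S4Vectors::subjectHits(hits)

  pos <- tss$pos[gi]
  s <- peaks$start[pj]
  e <- peaks$end[pj]
  # signed genomic distance to the nearest peak edge; 0 when spanning the TSS
  d_genomic <- ifelse(pos >= s & pos < e, 0L,
               ifelse(e <= pos, -(pos - (e - 1L)), s - pos))
  d <- ifelse(tss$strand[gi] == "+", d_genomic, -d_genomic)
  keep <- abs(d) <= window
  out <- tibble::tibble(
    gene = tss$gene[gi][keep],
    peak = peaks$peak[pj][keep],
    chrom = peaks$chrom[pj][keep],
    start = peaks$start[pj][keep],
    end = peaks$end[pj][keep],
    distance = as.numeric(d[keep]),
    side = ifelse(d[keep] < 0, "upstream", "downstream")
  )
  out <- dplyr::arrange(out, .data$gene, abs(.data$distance))
  attr(out, "window") <- window
  class(out) <- c("peak_gene_index", class(out))
  out
}

poisson_loglik <- function(y, mu) sum(stats::dpois(y, mu, log = TRUE))

fit_poisson_rp <- function(y, rp, log_libsize) {
  X <- cbind(1, rp)
  fit <- suppressWarnings(
    glm.fit(X, y, family = poisson(), offset = log_libsize,
            control = list(maxit = 100))
  )
  mu <- fit$fitted.values
  list(alpha = unname(fit$coefficients[1]),
       beta = unname(fit$coefficients[2]),
       loglik = poisson_loglik(y, mu))
}

fit_poisson_intercept <- function(y, log_libsize) {
  # closed form: rate = sum(y) / sum(libsize)
  lib <- exp(log_libsize)
  a <- log(sum(y) / sum(lib))
  if (!is.finite(a)) a <- -30
  list(alpha = a, beta = 0, loglik = poisson_loglik(y, lib * exp(a)))
}

#' Fit a per-gene regulatory-potential model
#'
#' Exhaustively searches a grid of upstream/downstream exponential decay
#' lengths; at each grid pair the peak weights are w_j = exp(-|d_j|/decay)
#' and the per-cell regulatory potential RP_c = sum_j w_j * acc_jc. The
#' intercept and RP coefficient are fitted by Poisson IRLS with a log
#' library-size offset, and the arg-max grid point is returned (ties broken
#' toward larger decay lengths, i.e. the smoother model).
#'
#' @param gene Gene ID present in `index`.
#' @param index A `peak_gene_index` from [link_peaks_to_genes()].
#' @param acc Peak x cell counts (rows named by peak).
#' @param expr Gene counts: the gene x cell matrix or the gene's count
#'   vector.
#' @param libsize Per-cell library-size scale (positive).
#' @param grid Decay-length grid in bp (see [decay_grid()]).
#' @return An `rp_model`: gene, decay_up, decay_down, peak table with
#'   weights, alpha, beta, loglik, loglik_null, degenerate flag.
#' @export
fit_rp_model <- function(gene, index, acc, expr, libsize,
                         grid = decay_grid()) {
  if (length(grid) == 0 || any(grid <= 0)) {
    stop_config("`grid` must be non-empty with all decay lengths > 0")
  }
  idx <- index[index$gene == gene, ]
  if (nrow(idx) == 0) stop_validate(sprintf("gene '%s' has no linked peaks", gene))
  y <- if (is.matrix(expr) || inherits(expr, "Matrix")) as.numeric(expr[gene, ]) else as.numeric(expr)
  missing_peaks <- setdiff(idx$peak, rownames(acc))
  if (length(missing_peaks) > 0) {
    stop_validate(sprintf("accessibility matrix lacks peak(s): %s",
                          paste(missing_peaks, collapse = ", ")))
  }
  A <- as.matrix(acc[idx$peak, , drop = FALSE])
  log_lib <- log(libsize)

  null_fit <- fit_poisson_intercept(y, log_lib)
  if (all(A == 0)) {
    return(new_rp_model(gene, grid[length(grid)], grid[length(grid)], idx,
                        null_fit$alpha, 0, null_fit$loglik, null_fit$loglik,
                        degenerate = TRUE, grid = grid))
  }

  up <- idx$side == "upstream"
  absd <- abs(idx$distance)
  # RP separates into an upstream and a downstream sum; precompute each
  rp_up <- lapply(grid, function(l) {
    if (!any(up)) rep(0, length(y)) else
      crossprod(A[up, , drop = FALSE], exp(-absd[up] / l))[, 1]
  })
  rp_down <- lapply(grid, function(l) {
    if (all(up)) rep(0, length(y)) else
      crossprod(A[!up, , drop = FALSE], exp(-absd[!up] / l))[, 1]
  })

  best <- NULL
  for (iu in seq_along(grid)) {
    for (id in seq_along(grid)) {
      rp <- rp_up[[iu]] + rp_down[[id]]
      fit <- fit_poisson_rp(y, rp, log_lib)
      # ties (within 1e-9) go to the larger decay pair: >= on later grid points
      if (is.null(best) || fit$loglik > best$loglik + 1e-9 ||
          (fit$loglik >= best$loglik - 1e-9 &&
           grid[iu] + grid[id] > best$lu + best$ld)) {
        best <- c(fit, list(lu = grid[iu], ld = grid[id]))
      }
    }
  }
  new_rp_model(gene, best$lu, best$ld, idx, best$alpha, best$beta,
               best$loglik, null_fit$loglik, degenerate = FALSE, grid = grid)
}

new_rp_model <- function(gene, lu, ld, idx, alpha, beta, loglik, loglik_null,
                         degenerate, grid) {
  idx$weight <- exp(-abs(idx$distance) / ifelse(idx$side == "upstream", lu, ld))
  structure(list(
    gene = gene, decay_up = lu, decay_down = ld,
    peaks = tibble::as_tibble(idx[, c("peak", "chrom", "start", "end",
                                      "distance", "side", "weight")]),
    alpha = alpha, beta = beta,
    loglik = loglik, loglik_null = loglik_null,
    degenerate = degenerate, grid = grid
  ), class = "rp_model")
}

#' @export
print.rp_model <- function(x, ...) {
  cat("<rp_model> ", x$gene, ": ", nrow(x$peaks), " peaks, decay up/down ",
      round(x$decay_up), "/", round(x$decay_down), " bp, beta ",
      signif(x$beta, 3), if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Per-cell regulatory-potential scores
#'
#' RP_c = sum_j w_j * acc_jc over the model's peaks: nonnegative and linear
#' in accessibility.
#'
#' @param model An `rp_model`.
#' @param acc Peak x cell counts covering all model peaks.
#' @return Named numeric vector of per-cell RP values.
#' @export
rp_scores <- function(model, acc) {
  stopifnot(inherits(model, "rp_model"))
  missing_peaks <- setdiff(model$peaks$peak, rownames(acc))
  if (length(missing_peaks) > 0) {
    stop_validate(sprintf("accessibility matrix lacks model peak(s): %s",
                          paste(missing_peaks, collapse = ", ")))
  }
  A <- as.matrix(acc[model$peaks$peak, , drop = FALSE])
  setNames(crossprod(A, model$peaks$weight)[, 1], colnames(acc))
}
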