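#' Differential expression between knockout and control cells
#'
#' Per gene: log2 fold change of mean library-size-normalized expression
#' (pseudocount 1e-9), two-sided Wilcoxon rank-sum p-value, and
#' Benjamini-Hochberg FDR. Genes with all-zero counts in both groups get
#' FC = 0, p = 1.
#'
#' @param counts Gene x cell count matrix.
#' @param group_ko,group_ctl Cell IDs (or column indices) of the two
#'   groups; both non-empty.
#' @param pseudocount Added to both means before the ratio.
#' @return Tibble: gene, log2fc, p, fdr.
#' @export
deg_stats <- function(counts, group_ko, group_ctl, pseudocount = 1e-9) {
  M <- as.matrix(counts)
  ko <- resolve_cells(group_ko, colnames(M), ncol(M))
  ctl <- resolve_cells(group_ctl, colnames(M), ncol(M))
  if (length(ko) == 0 || length(ctl) == 0) {
    stop_validate("both cell groups must be non-empty")
  }
  lib <- colSums(M)
  lib[lib == 0] <- 1
  N <- sweep(M, 2, lib / stats::median(lib), "/")
  m_ko <- rowMeans(N[, ko, drop = FALSE])
  m_ctl <- rowMeans(N[, ctl, drop = FALSE])
  zero <- rowSums(M[, c(ko, ctl), drop = FALSE]) == 0
  log2fc <- ifelse(zero, 0, log2((m_ko + pseudocount) / (m_ctl + pseudocount)))
  p <- vapply(seq_len(nrow(N)), function(i) {
    if (zero[i]) return(1)
    suppressWarnings(
      wilcox.test(N[i, ko], N[i, ctl], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  tibble::tibble(gene = rownames(M) %||% as.character(seq_len(nrow(M))),
                 log2fc = log2fc, p = p, fdr = p.adjust(p, "BH"))
}

resolve_cells <- function(group, cn, n) {
  if (is.numeric(group)) return(group[group >= 1 & group <= n])
  which(cn %in% group)
}

#' Concordant differentially expressed genes across two replicates
#'
#' A gene is kept iff in BOTH replicates |linear FC| > `fc_cut` (strict),
#' FDR <= `fdr_cut` (inclusive), and the fold-change signs agree.
#'
#' @param rep1,rep2 Per-replicate tibbles from [deg_stats()] (gene, log2fc,
#'   fdr) over a shared gene universe.
#' @param fc_cut Linear fold-change threshold (default 1.25, i.e.
#'   |log2fc| > log2(1.25)).
#' @param fdr_cut FDR threshold (default 0.05, inclusive).
#' @return A `deg_tbl` tibble: gene, log2fc_rep1, log2fc_rep2, mean_log2fc,
#'   direction ("up"/"down").
#' @export
concordant_degs <- function(rep1, rep2, fc_cut = 1.25, fdr_cut = 0.05) {
  j <- dplyr::inner_join(
    rep1[, c("gene", "log2fc", "fdr")],
    rep2[, c("gene", "log2fc", "fdr")],
    by = "gene", suffix = c("_rep1", "_rep2"))
  lcut <- log2(fc_cut)
  keep <- abs(j$log2fc_rep1) > lcut & abs(j$log2fc_rep2) > lcut &
    j$fdr_rep1 <= fdr_cut & j$fdr_rep2 <= fdr_cut &
    sign(j$log2fc_rep1) == sign(j$log2fc_rep2)
  out <- j[keep, c("gene", "log2fc_rep1", "log2fc_rep2")]
  out$mean_log2fc <- (out$log2fc_rep1 + out$log2fc_rep2) / 2
  out$direction <- ifelse(out$mean_log2fc > 0, "up", "down")
  out <- tibble::as_tibble(out)
  attr(out, "fc_cut") <- fc_cut
  attr(out, "fdr_cut") <- fdr_cut
  class(out) <- c("deg_tbl", class(out))
  out
}
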