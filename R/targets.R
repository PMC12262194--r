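#' Seqlet-anchored regulatory-potential scores for TF targets
#'
#' For every (TF, concordant DEG) pair: finds the gene's linked cCREs that
#' contain at least one seqlet (1 bp overlap) of a motif family the TF
#' binds, and sums those cCREs' regulatory-potential weights. A gene is a
#' direct target when it is a DEG and at least one of its cCREs carries a
#' cognate seqlet (score > 0). DEGs without a fitted RP model are flagged
#' and excluded from direct targets.
#'
#' @param degs A `deg_tbl` from [concordant_degs()].
#' @param models Named list of `rp_model`s.
#' @param seqlets Seqlet intervals: tibble with chrom, start, end, family
#'   (0-based half-open; e.g. from [scan_composite_elements()] lifted to
#'   genomic coordinates, or a seqlet BED).
#' @param family_map Named list TF -> character vector of motif families.
#' @param index Unused placeholder kept for peak provenance; linked cCREs
#'   and weights come from each gene's `rp_model`.
#' @return Tibble: tf, gene, rp_score, n_seqlet_cres, direct_target,
#'   flagged.
#' @export
rp_score_targets <- function(degs, models, seqlets, family_map, index = NULL) {
  stopifnot(is.list(family_map), !is.null(names(family_map)))
  purrr::imap_dfr(family_map, function(fams, tf) {
    sq <- seqlets[seqlets$family %in% fams, , drop = FALSE]
    purrr::map_dfr(degs$gene, function(g) {
      model <- models[[g]]
      if (is.null(model)) {
        return(tibble::tibble(tf = tf, gene = g, rp_score = NA_real_,
                              n_seqlet_cres = NA_integer_,
                              direct_target = FALSE, flagged = TRUE))
      }
      hit <- overlaps_any(model$peaks, sq[, c("chrom", "start", "end")])
      score <- sum(model$peaks$weight[hit])
      tibble::tibble(tf = tf, gene = g, rp_score = score,
                     n_seqlet_cres = sum(hit),
                     direct_target = score > 0, flagged = FALSE)
    })
  })
}

#' Overlap of two gene sets in a universe
#'
#' 2x2 membership table, two-sided Fisher exact p, and the sample odds
#' ratio with a 0.5 continuity correction when any cell is zero.
#'
#' @param set_a,set_b Gene sets, subsets of `universe`.
#' @param universe Background gene set (non-empty).
#' @return One-row tibble: n_a, n_b, n_overlap, odds_ratio, p, fdr (= p for
#'   a single pair).
#' @export
target_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop_validate("`universe` must be non-empty")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop_validate("both sets must be subsets of the universe")
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  p <- fisher.test(m, alternative = "two.sided")$p.value
  or <- if (any(m == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  tibble::tibble(n_a = length(set_a), n_b = length(set_b), n_overlap = a,
                 odds_ratio = or, p = p, fdr = p)
}

#' All pairwise overlaps among named gene sets, with BH correction
#'
#' @param sets Named list of gene sets.
#' @param universe Background gene set.
#' @return Tibble with one row per unordered pair; `fdr` is BH-adjusted
#'   across all pairs tested in the batch.
#' @export
pairwise_target_overlap <- function(sets, universe) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    dplyr::mutate(target_overlap(sets[[pr[1]]], sets[[pr[2]]], universe),
                  set_a = pr[1], set_b = pr[2], .before = 1)
  })
  out$fdr <- p.adjust(out$p, "BH")
  out
}
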