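#' Simulate peak DNA sequences with planted composite elements
#'
#' Draws a random DNA sequence for every peak and plants, in each cCRE with a
#' planted TF binding, one instance of the bound TF's motif-family consensus
#' (ISRE for pro-PB TFs, EICE for pro-GC TFs, AP1 for housekeeping TFs) at a
#' recorded position, on a random strand. The recorded seqlet intervals are
#' the ground truth for the composite-element scanner and for seqlet-anchored
#' target calling.
#'
#' @param dataset A `multiome_dataset`.
#' @param seed Integer seed.
#' @return List with `sequences` (named [Biostrings::DNAStringSet], one per
#'   peak) and `seqlets` (tibble: chrom, start, end, strand, family, peak;
#'   genomic 0-based half-open coordinates).
#' @export
simulate_peak_sequences <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "multiome_dataset"))
  set.seed(seed)
  peaks <- dataset$peaks
  cres <- dataset$truth$cres
  fam_of_tf <- setNames(dataset$truth$tfs$motif_family, dataset$truth$tfs$tf)

  consensus <- c(
    ISRE = "GAAANNGAAA", EICE = "GGAANNGAAA", AP1 = "TGASTCA",
    PRDM1 = "GAAAGTGAAAGT"
  )
  bases <- c("A", "C", "G", "T")

  seqs <- character(nrow(peaks))
  seqlet_rows <- list()
  for (j in seq_len(nrow(peaks))) {
    width <- peaks$end[j] - peaks$start[j]
    s <- sample(bases, width, TRUE)
    bt <- cres$bound_tfs[[match(peaks$peak[j], cres$cre)]]
    if (length(bt) > 0) {
      fams <- unique(fam_of_tf[bt])
      pos <- 10L
      for (fam in fams) {
        inst <- instantiate_consensus(consensus[[fam]])
        minus <- runif(1) < 0.5
        planted <- if (minus) as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(inst))) else inst
        nc <- nchar(planted)
        if (pos + nc - 1L > width) break
        s[pos:(pos + nc - 1L)] <- strsplit(planted, "")[[1]]
        seqlet_rows[[length(seqlet_rows) + 1L]] <- tibble::tibble(
          chrom = peaks$chrom[j],
          start = peaks$start[j] + pos - 1L,
          end = peaks$start[j] + pos - 1L + nc,
          strand = if (minus) "-" else "+",
          family = fam, peak = peaks$peak[j]
        )
        pos <- pos + nc + 10L
      }
    }
    seqs[j] <- paste(s, collapse = "")
  }
  sequences <- Biostrings::DNAStringSet(setNames(seqs, peaks$peak))
  seqlets <- if (length(seqlet_rows)) dplyr::bind_rows(seqlet_rows) else
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), family = character(), peak = character())
  list(sequences = sequences, seqlets = seqlets)
}

instantiate_consensus <- function(pat) {
  expand <- c(N = "ACGT", S = "CG", W = "AT", R = "AG", Y = "CT", M = "AC", K = "GT")
  ch <- strsplit(pat, "")[[1]]
  out <- vapply(ch, function(x) {
    if (x %in% names(expand)) {
      opts <- strsplit(expand[[x]], "")[[1]]
      sample(opts, 1)
    } else x
  }, character(1))
  paste(out, collapse = "")
}

#' Simulate paired differential-expression replicate tables for a TF knockout
#'
#' Planted targets of the knocked-out TF receive a true log2 fold change of
#' opposite sign to the planted regulatory sign (knocking out an activator
#' lowers its targets); both replicates share the true effects and add
#' independent Gaussian noise, mirroring a two-replicate KO experiment.
#'
#' @param truth A `true_grn`.
#' @param tf TF whose knockout is emulated.
#' @param effect_scale Log2-fold-change per unit planted effect.
#' @param sigma Per-replicate noise standard deviation (also the test se).
#' @param seed Integer seed.
#' @return List of two tibbles (`rep1`, `rep2`), each with gene, log2fc, p,
#'   fdr, plus `true_lfc`, the planted per-gene truth.
#' @export
simulate_deg_replicates <- function(truth, tf, effect_scale = 1, sigma = 0.12,
                                    seed = 1L) {
  stopifnot(inherits(truth, "true_grn"))
  if (!tf %in% truth$tfs$tf) stop_validate(sprintf("unknown TF '%s'", tf))
  set.seed(seed)
  genes <- truth$genes$gene
  true_lfc <- setNames(numeric(length(genes)), genes)
  e <- truth$edges[truth$edges$tf == tf, ]
  true_lfc[e$gene] <- -e$sign * e$effect * effect_scale
  one_rep <- function() {
    obs <- true_lfc + rnorm(length(genes), 0, sigma)
    p <- 2 * pnorm(-abs(obs) / sigma)
    tibble::tibble(gene = genes, log2fc = unname(obs), p = p,
                   fdr = p.adjust(p, "BH"))
  }
  list(rep1 = one_rep(), rep2 = one_rep(), true_lfc = true_lfc)
}
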