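#' Scan DNA sequences for composite IRF elements and related motifs
#'
#' Exact IUPAC-consensus matching on both strands. Simple families are
#' single consensus strings (EICE = GGAANNGAAA, ISRE = GAAANNGAAA,
#' AP1 = TGASTCA, PRDM1 = GAAAGTGAAAGT, ETS configurable); the composite
#' AICE is an AP1 and a GAAA half-site co-occurring with a gap of
#' `aice_gap` bp in either order, and PRDM1_IRF is an overlapping
#' PRDM1/ISRE pair. Minus-strand hits are reported in plus-strand
#' coordinates; palindromic consensi are scanned once. Coordinates are
#' 0-based half-open.
#'
#' @param sequences Named character vector, [Biostrings::DNAStringSet], or
#'   path to a FASTA file. Letters must be IUPAC A/C/G/T/N after
#'   upper-casing.
#' @param families Families to scan (subset of the default set).
#' @param ets_consensus Consensus used for the ETS family (core GGAA with
#'   flanks; IUPAC allowed).
#' @param aice_gap Allowed gap range (bp) between the AICE half-sites.
#' @return A `seqlet_tbl` tibble: seqname, start, end, strand, family,
#'   match (plus-strand substring for "+", its reverse complement for "-",
#'   the spanned substring for composite "*" hits).
#' @export
scan_composite_elements <- function(sequences,
                                    families = c("EICE", "ISRE", "AP1", "ETS",
                                                 "PRDM1", "AICE", "PRDM1_IRF"),
                                    ets_consensus = "MGGAAR",
                                    aice_gap = c(0, 4)) {
  families <- match.arg(families, several.ok = TRUE)
  seqs <- as_dna_set(sequences)
  check_iupac(seqs)

  consensus <- c(EICE = "GGAANNGAAA", ISRE = "GAAANNGAAA", AP1 = "TGASTCA",
                 PRDM1 = "GAAAGTGAAAGT", ETS = toupper(ets_consensus))
  simple <- intersect(families, names(consensus))
  need_ap1 <- "AICE" %in% families
  need_isre_prdm1 <- "PRDM1_IRF" %in% families

  hit_tbl <- function(fam, pat) {
    dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
      scan_one(seqs[[i]], names(seqs)[i], fam, pat)
    }))
  }
  hits <- dplyr::bind_rows(lapply(simple, function(f) hit_tbl(f, consensus[[f]])))

  aux <- list()
  if (need_ap1 && !"AP1" %in% simple) aux$AP1 <- hit_tbl("AP1", consensus[["AP1"]])
  if (need_isre_prdm1) {
    if (!"ISRE" %in% simple) aux$ISRE <- hit_tbl("ISRE", consensus[["ISRE"]])
    if (!"PRDM1" %in% simple) aux$PRDM1 <- hit_tbl("PRDM1", consensus[["PRDM1"]])
  }
  pool <- dplyr::bind_rows(hits, dplyr::bind_rows(aux))

  if (need_ap1) {
    half <- hit_tbl("GAAA_half", "GAAA")
    ap1 <- pool[pool$family == "AP1", ]
    hits <- dplyr::bind_rows(hits,
      pair_composite(ap1, half, "AICE", gap = aice_gap, seqs = seqs))
  }
  if (need_isre_prdm1) {
    hits <- dplyr::bind_rows(hits,
      pair_composite(pool[pool$family == "PRDM1", ],
                     pool[pool$family == "ISRE", ],
                     "PRDM1_IRF", overlap = TRUE, seqs = seqs))
  }
  hits <- hits[hits$family %in% families, ]
  hits <- dplyr::arrange(hits, .data$seqname, .data$start, .data$end,
                         .data$family, .data$strand)
  class(hits) <- c("seqlet_tbl", class(hits))
  hits
}

as_dna_set <- function(sequences) {
  if (is(sequences, "DNAStringSet")) return(sequences)
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences)) {
    return(Biostrings::readDNAStringSet(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop_validate(sprintf("non-IUPAC (non-ACGTN) characters in record(s): %s",
                          paste(names(sequences)[bad], collapse = ", ")))
  }
  Biostrings::DNAStringSet(sequences)
}

check_iupac <- function(seqs) {
  freq <- Biostrings::alphabetFrequency(seqs)
  ok <- c("A", "C", "G", "T", "N")
  extra <- freq[, setdiff(colnames(freq), ok), drop = FALSE]
  bad <- rowSums(extra) > 0
  if (any(bad)) {
    stop_validate(sprintf("non-IUPAC (non-ACGTN) characters in record(s): %s",
                          paste(names(seqs)[bad], collapse = ", ")))
  }
}

scan_one <- function(seq, seqname, family, pattern) {
  pat <- Biostrings::DNAString(pattern)
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(pat) == as.character(rc)
  plus <- Biostrings::matchPattern(pat, seq, fixed = FALSE)
  rows <- list()
  if (length(plus) > 0) {
    rows$p <- tibble::tibble(
      seqname = seqname, start = Biostrings::start(plus) - 1L,
      end = Biostrings::end(plus), strand = "+", family = family,
      match = as.character(plus))
  }
  if (!palindromic) {
    minus <- Biostrings::matchPattern(rc, seq, fixed = FALSE)
    if (length(minus) > 0) {
      rows$m <- tibble::tibble(
        seqname = seqname, start = Biostrings::start(minus) - 1L,
        end = Biostrings::end(minus), strand = "-", family = family,
        match = as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(minus))))
    }
  }
  if (length(rows) == 0) empty_hits() else dplyr::bind_rows(rows)
}

empty_hits <- function() {
  tibble::tibble(seqname = character(), start = integer(), end = integer(),
                 strand = character(), family = character(), match = character())
}

#' Lift peak-local scan hits to genomic coordinates
#'
#' Scan hits on peak sequences are relative to each peak's start; this adds
#' the peak offset to produce genomic seqlet intervals.
#'
#' @param hits A `seqlet_tbl` whose `seqname`s are peak IDs.
#' @param peaks Peak table: peak, chrom, start, end (0-based half-open).
#' @return Tibble: chrom, start, end, strand, family, peak.
#' @export
seqlets_to_genomic <- function(hits, peaks) {
  i <- match(hits$seqname, peaks$peak)
  if (anyNA(i)) stop_validate("scan hit on a sequence absent from the peak table")
  tibble::tibble(
    chrom = peaks$chrom[i],
    start = peaks$start[i] + hits$start,
    end = peaks$start[i] + hits$end,
    strand = hits$strand, family = hits$family, peak = hits$seqname
  )
}

# pair two hit sets into a composite: gap in [gap1, gap2] in either order,
# or any >= 1 bp overlap when overlap = TRUE; span reported on strand "*"
pair_composite <- function(a, b, family, gap = c(0, 4), overlap = FALSE,
                           seqs = NULL) {
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_hits())
  out <- list()
  for (sn in intersect(unique(a$seqname), unique(b$seqname))) {
    aa <- a[a$seqname == sn, ]; bb <- b[b$seqname == sn, ]
    for (i in seq_len(nrow(aa))) for (j in seq_len(nrow(bb))) {
      if (overlap) {
        hit <- aa$start[i] < bb$end[j] && bb$start[j] < aa$end[i]
      } else {
        g <- if (bb$start[j] >= aa$end[i]) bb$start[j] - aa$end[i]
             else if (aa$start[i] >= bb$end[j]) aa$start[i] - bb$end[j]
             else -1L
        hit <- g >= gap[1] && g <= gap[2]
      }
      if (hit) {
        s <- min(aa$start[i], bb$start[j]); e <- max(aa$end[i], bb$end[j])
        m <- if (!is.null(seqs) && sn %in% names(seqs)) {
          as.character(Biostrings::subseq(seqs[[sn]], s + 1L, e))
        } else NA_character_
        out[[length(out) + 1L]] <- tibble::tibble(
          seqname = sn, start = s, end = e, strand = "*",
          family = family, match = m)
      }
    }
  }
  if (length(out) == 0) empty_hits() else
    dplyr::distinct(dplyr::bind_rows(out))
}
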