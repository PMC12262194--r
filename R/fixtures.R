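#' Write a synthetic dataset to standard on-disk formats
#'
#' Emits counts as MatrixMarket, labels and metadata as TSV, intervals as
#' 0-based half-open BED, sequences as FASTA, and the planted truth as JSON,
#' then returns a manifest with an MD5 checksum per file. The layout is a
#' plain-text mirror of a 10x-style multiome directory plus ground truth.
#'
#' @param dataset A `multiome_dataset`.
#' @param truth The `true_grn` behind it (defaults to `dataset$truth`).
#' @param out_dir Output directory, created if needed.
#' @param sequences Optional result of [simulate_peak_sequences()]; when
#'   given, `sequences.fa` and `seqlets.bed` are written too.
#' @return Tibble manifest: `file`, `md5`.
#' @export
emit_fixtures <- function(dataset, truth = dataset$truth, out_dir,
                          sequences = NULL) {
  stopifnot(inherits(dataset, "multiome_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    rlang::abort(sprintf("output directory '%s' is not writable", out_dir),
                 class = "bifurcgrn_io_error")
  }
  p <- function(f) file.path(out_dir, f)

  Matrix::writeMM(Matrix::Matrix(dataset$expr, sparse = TRUE), p("expr.mtx"))
  Matrix::writeMM(Matrix::Matrix(dataset$acc, sparse = TRUE), p("acc.mtx"))
  readr::write_tsv(tibble::tibble(gene = rownames(dataset$expr)), p("expr_rows.tsv"))
  readr::write_tsv(tibble::tibble(peak = rownames(dataset$acc)), p("acc_rows.tsv"))
  readr::write_tsv(dataset$cells, p("cells.tsv"))
  tss <- dataset$genes[, c("chrom", "tss", "strand", "gene")]
  names(tss)[2] <- "pos"
  readr::write_tsv(tss, p("tss.tsv"))
  write_bed(dataset$peaks[, c("chrom", "start", "end", "peak")], p("peaks.bed"))

  tfb <- tf_binding_sets(dataset)
  bed <- purrr::imap_dfr(tfb, function(sets, tf) {
    dplyr::mutate(dplyr::bind_rows(sets), name = tf)
  })
  write_bed(bed, p("tf_binding.bed"))

  if (!is.null(sequences)) {
    Biostrings::writeXStringSet(sequences$sequences, p("sequences.fa"))
    write_bed(sequences$seqlets[, c("chrom", "start", "end", "family", "strand")],
              p("seqlets.bed"))
  }

  jsonlite::write_json(truth_to_list(truth), p("truth.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  readr::write_tsv(manifest, p("manifest.tsv"))
  manifest
}

write_bed <- function(df, path) {
  if (nrow(df) > 0) {
    ord <- order(df$chrom, df$start, df$end)
    df <- df[ord, ]
  }
  readr::write_tsv(df, path, col_names = FALSE)
  # header-only marker for empty tables so round-trips keep column shape
  if (nrow(df) == 0) writeLines(character(0), path)
  invisible(path)
}

truth_to_list <- function(truth) {
  list(
    tfs = truth$tfs,
    genes = truth$genes,
    cres = dplyr::mutate(truth$cres,
      bound_tfs = purrr::map(.data$bound_tfs, as.character)),
    edges = truth$edges,
    params = truth$params
  )
}

#' Read back fixtures written by [emit_fixtures()]
#'
#' @param dir Directory written by [emit_fixtures()].
#' @return List with `expr`, `acc` (sparse matrices with dimnames), `cells`,
#'   `tss`, `peaks`, `tf_binding`, and (when present) `seqlets` tibbles and
#'   `sequences`; `truth` as a plain list.
#' @export
read_fixtures <- function(dir) {
  p <- function(f) file.path(dir, f)
  expr <- methods::as(Matrix::readMM(p("expr.mtx")), "CsparseMatrix")
  acc <- methods::as(Matrix::readMM(p("acc.mtx")), "CsparseMatrix")
  cells <- readr::read_tsv(p("cells.tsv"), show_col_types = FALSE)
  rownames(expr) <- readr::read_tsv(p("expr_rows.tsv"), show_col_types = FALSE)$gene
  rownames(acc) <- readr::read_tsv(p("acc_rows.tsv"), show_col_types = FALSE)$peak
  colnames(expr) <- colnames(acc) <- cells$cell
  out <- list(
    expr = expr, acc = acc, cells = cells,
    tss = readr::read_tsv(p("tss.tsv"), show_col_types = FALSE),
    peaks = read_bed(p("peaks.bed"), c("chrom", "start", "end", "peak")),
    tf_binding = read_bed(p("tf_binding.bed"), c("chrom", "start", "end", "name")),
    truth = jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  )
  if (file.exists(p("seqlets.bed"))) {
    out$seqlets <- read_bed(p("seqlets.bed"),
                            c("chrom", "start", "end", "family", "strand"))
  }
  if (file.exists(p("sequences.fa"))) {
    out$sequences <- Biostrings::readDNAStringSet(p("sequences.fa"))
  }
  out
}

read_bed <- function(path, col_names) {
  df <- readr::read_tsv(path, col_names = col_names, show_col_types = FALSE)
  for (cc in intersect(c("start", "end"), col_names)) df[[cc]] <- as.integer(df[[cc]])
  if (nrow(df) == 0) {
    df <- tibble::as_tibble(setNames(
      lapply(col_names, function(x) if (x %in% c("start", "end")) integer() else character()),
      col_names))
  }
  df
}
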