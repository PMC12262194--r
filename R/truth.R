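#' Generate a ground-truth regulatory network for simulation
#'
#' Builds the planted truth that drives the synthetic multiome generator: a
#' set of transcription factors split into pro-plasmablast (pro_PB), pro-
#' germinal-center (pro_GC) and housekeeping roles; regulated genes split
#' into a PB program and a GC program; and per-gene candidate cis-regulatory
#' elements (cCREs) at signed distances from the TSS, each bound by a subset
#' of TFs with a signed binding strength. Pro-PB TFs activate PB-program
#' genes and repress GC-program genes, and vice versa, planting the mutual-
#' repression toggle that underlies the fate bifurcation. Each regulated
#' gene additionally carries one decoy cCRE bound only by a housekeeping TF
#' with no effect on expression, so that in-silico deletion of a bystander
#' TF has a planted null.
#'
#' @param n_tf Number of TFs (>= 4; at least one pro-PB and one pro-GC).
#' @param n_gene Number of genes (TF-coding genes are added on top).
#' @param n_cre_per_gene cCREs per regulated gene (functional ones; a decoy
#'   is added when housekeeping TFs exist).
#' @param window Maximum |TSS distance| of a planted cCRE, bp.
#' @param seed Integer seed; identical seeds give identical truth.
#' @param n_cre_hk cCREs for housekeeping genes (no planted edges); default 0.
#' @param frac_hk_gene Fraction of genes that are housekeeping.
#' @param decay_range Range (bp) from which per-gene decay lengths are drawn
#'   log-uniformly; a degenerate range plants a fixed decay length.
#' @param effect_range Range of planted TF-to-gene effect magnitudes.
#' @return A `true_grn` list: `tfs` (tibble: tf, role, motif_family),
#'   `genes` (tibble: gene, class, program, decay_up, decay_down),
#'   `cres` (tibble: gene, cre, distance, strength, bound_tfs list-column),
#'   `edges` (tibble: tf, gene, sign, effect), and the call parameters.
#' @export
generate_true_grn <- function(n_tf, n_gene, n_cre_per_gene = 4, window = 1e5,
                              seed = 1L, n_cre_hk = 0, frac_hk_gene = 0.2,
                              decay_range = c(2000, 30000),
                              effect_range = c(0.5, 1.5)) {
  n_tf <- assert_count(n_tf, "n_tf", min = 0L)
  if (n_tf < 4L) {
    stop_config("`n_tf` must be >= 4: at least one pro-PB, one pro-GC and two housekeeping TFs are required")
  }
  n_gene <- assert_count(n_gene, "n_gene", min = 1L)
  n_cre_per_gene <- assert_count(n_cre_per_gene, "n_cre_per_gene")
  if (window <= 0) stop_config("`window` must be > 0")

  set.seed(seed)

  n_pb <- max(1L, floor(n_tf * 0.35))
  n_gc <- max(1L, floor(n_tf * 0.35))
  n_hk <- n_tf - n_pb - n_gc
  roles <- c(rep("pro_PB", n_pb), rep("pro_GC", n_gc), rep("housekeeping", n_hk))
  tfs <- tibble::tibble(
    tf = sprintf("TF%02d", seq_len(n_tf)),
    role = roles,
    motif_family = dplyr::case_when(
      roles == "pro_PB" ~ "ISRE",
      roles == "pro_GC" ~ "EICE",
      TRUE ~ "AP1"
    )
  )

  n_hk_gene <- round(n_gene * frac_hk_gene)
  gene_class <- c(rep("regulated", n_gene - n_hk_gene), rep("housekeeping", n_hk_gene))
  program <- ifelse(gene_class == "regulated",
    rep_len(c("PB", "GC"), n_gene), NA_character_
  )
  ldec <- exp(runif(n_gene, log(decay_range[1]), log(decay_range[2])))
  ldec2 <- exp(runif(n_gene, log(decay_range[1]), log(decay_range[2])))
  genes <- tibble::tibble(
    gene = sprintf("G%03d", seq_len(n_gene)),
    class = gene_class,
    program = program,
    decay_up = ldec,
    decay_down = ldec2
  )

  pb_tfs <- tfs$tf[tfs$role == "pro_PB"]
  gc_tfs <- tfs$tf[tfs$role == "pro_GC"]
  hk_tfs <- tfs$tf[tfs$role == "housekeeping"]

  cre_rows <- list()
  edge_rows <- list()
  for (i in seq_len(n_gene)) {
    g <- genes$gene[i]
    if (genes$class[i] == "housekeeping") {
      n_cre <- n_cre_hk
      if (n_cre > 0) {
        d <- sample(c(-1, 1), n_cre, TRUE) * round(exp(runif(n_cre, log(200), log(window * 0.8))))
        cre_rows[[length(cre_rows) + 1L]] <- tibble::tibble(
          gene = g, cre = sprintf("%s_cre%d", g, seq_len(n_cre)),
          distance = d, strength = 0,
          bound_tfs = replicate(n_cre, character(0), simplify = FALSE)
        )
      }
      next
    }
    act_tfs <- if (program[i] == "PB") pb_tfs else gc_tfs
    rep_tfs <- if (program[i] == "PB") gc_tfs else pb_tfs
    # at least one activator and one repressor per regulated gene
    act_pick <- sample(act_tfs, min(length(act_tfs), max(1L, rbinom(1, length(act_tfs), 0.6))))
    rep_pick <- sample(rep_tfs, min(length(rep_tfs), max(1L, rbinom(1, length(rep_tfs), 0.6))))
    picked <- c(act_pick, rep_pick)
    sgn <- c(rep(1, length(act_pick)), rep(-1, length(rep_pick)))
    eff <- runif(length(picked), effect_range[1], effect_range[2])
    edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
      tf = picked, gene = g, sign = sgn, effect = eff
    )
    n_cre <- max(n_cre_per_gene, 1L)
    d <- sample(c(-1, 1), n_cre, TRUE) * round(exp(runif(n_cre, log(200), log(window * 0.8))))
    d[1] <- sample(c(-1, 1), 1) * round(runif(1, 200, 2000)) # keep one proximal cCRE
    # distribute bound TFs over functional cCREs so every planted edge has a cCRE
    assign_idx <- rep_len(seq_len(n_cre), length(picked))
    bound <- lapply(seq_len(n_cre), function(j) picked[assign_idx == j])
    strength <- runif(n_cre, 0.6, 1.2)
    cre <- tibble::tibble(
      gene = g, cre = sprintf("%s_cre%d", g, seq_len(n_cre)),
      distance = d, strength = strength, bound_tfs = bound
    )
    if (length(hk_tfs) > 0) {
      decoy <- tibble::tibble(
        gene = g, cre = sprintf("%s_decoy", g),
        distance = sample(c(-1, 1), 1) * round(runif(1, 500, window * 0.5)),
        strength = 0,
        bound_tfs = list(sample(hk_tfs, 1))
      )
      cre <- dplyr::bind_rows(cre, decoy)
    }
    cre_rows[[length(cre_rows) + 1L]] <- cre
  }

  out <- structure(list(
    tfs = tfs,
    genes = genes,
    cres = if (length(cre_rows)) dplyr::bind_rows(cre_rows) else
      tibble::tibble(gene = character(), cre = character(), distance = numeric(),
                     strength = numeric(), bound_tfs = list()),
    edges = if (length(edge_rows)) dplyr::bind_rows(edge_rows) else
      tibble::tibble(tf = character(), gene = character(), sign = numeric(), effect = numeric()),
    params = list(n_tf = n_tf, n_gene = n_gene, n_cre_per_gene = n_cre_per_gene,
                  window = window, seed = seed)
  ), class = "true_grn")
  validate_true_grn(out)
  out
}

validate_true_grn <- function(truth) {
  stopifnot(inherits(truth, "true_grn"))
  reg <- truth$genes$gene[truth$genes$class == "regulated"]
  has_cre <- reg %in% truth$cres$gene
  if (!all(has_cre)) stop_validate("regulated gene without any cCRE in truth")
  if (nrow(truth$edges)) {
    ok <- purrr::map2_lgl(truth$edges$tf, truth$edges$gene, function(tf, g) {
      bt <- truth$cres$bound_tfs[truth$cres$gene == g]
      any(vapply(bt, function(b) tf %in% b, logical(1)))
    })
    if (!all(ok)) stop_validate("planted edge whose TF binds no cCRE of its target")
  }
  invisible(truth)
}

#' @export
print.true_grn <- function(x, ...) {
  cat("<true_grn> ", nrow(x$tfs), " TFs, ", nrow(x$genes), " genes, ",
      nrow(x$cres), " cCREs, ", nrow(x$edges), " planted edges\n", sep = "")
  invisible(x)
}
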