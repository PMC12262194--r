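#' Simulate a bifurcating single-cell multiome dataset
#'
#' Generates paired gene x cell and peak x cell counts from a planted truth.
#' Cells sit on a bifurcating trajectory (trunk of activated cells splitting
#' into a GC and a PB branch at `branch_point`); planted TF activities follow
#' logistic profiles in pseudotime, branch-specific after the branch point.
#' Peak counts are Poisson with log-rate = basal + sum of signed binding
#' strengths times TF activity; gene counts are Poisson with log-rate =
#' alpha + beta * RP + log(library size), where the regulatory potential
#' RP is the decay-weighted sum exp(-|d|/decay) * accessibility over the
#' gene's cCREs. The 2-D embedding is (pseudotime, signed branch offset)
#' plus Gaussian noise, so the differentiation gradient has a closed form.
#'
#' @param truth A `true_grn` from [generate_true_grn()].
#' @param n_cells Number of cells.
#' @param branch_point Pseudotime of the bifurcation, in (0, 1).
#' @param noise List of noise parameters: `embedding_sd`, `activity_sd`,
#'   `libsize_sd`, and optional `nb_size` switching counts to gamma-mixed
#'   Poisson (negative binomial) overdispersion.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param base_expr_effect Log-rate change of a gene per standard deviation
#'   of its regulatory potential, scaled by the gene's mean planted effect.
#' @return A `multiome_dataset`: sparse `expr` (gene x cell, TF-coding genes
#'   included as rows) and `acc` (peak x cell) counts, `cells`, `genes`,
#'   `peaks` tibbles, the per-cell `tf_activity` matrix, and `truth`.
#' @export
simulate_multiome <- function(truth, n_cells, branch_point = 0.4,
                              noise = list(), seed = 1L,
                              base_expr_effect = 1) {
  stopifnot(inherits(truth, "true_grn"))
  n_cells <- assert_count(n_cells, "n_cells", min = 1L)
  if (branch_point <= 0 || branch_point >= 1) {
    stop_config("`branch_point` must lie strictly between 0 and 1")
  }
  if (any(truth$genes$decay_up <= 0) || any(truth$genes$decay_down <= 0)) {
    stop_validate("nonpositive decay length in truth")
  }
  nz <- list(embedding_sd = 0.02, activity_sd = 0.05, libsize_sd = 0.3, nb_size = NULL)
  nz[names(noise)] <- noise

  set.seed(seed)

  t <- sort(runif(n_cells))
  branch <- ifelse(t < branch_point, "trunk",
                   sample(c("GC", "PB"), n_cells, TRUE))
  state <- ifelse(branch == "trunk", "ActB", branch)
  off <- pmax(t - branch_point, 0)
  y <- ifelse(branch == "GC", off, ifelse(branch == "PB", -off, 0))
  cells <- tibble::tibble(
    cell = sprintf("C%04d", seq_len(n_cells)),
    state = state, pseudotime = t, branch = branch,
    x = t + rnorm(n_cells, 0, nz$embedding_sd),
    y = y + rnorm(n_cells, 0, nz$embedding_sd),
    clonotype = NA_character_,
    replicate = "R1",
    libsize = exp(rnorm(n_cells, 0, nz$libsize_sd))
  )

  # latent TF activities: logistic in pseudotime, branch-specific after split
  n_tf <- nrow(truth$tfs)
  x0 <- branch_point + 0.15 + runif(n_tf, -0.08, 0.08)
  sl <- runif(n_tf, 0.06, 0.12)
  act <- matrix(0.5, n_tf, n_cells, dimnames = list(truth$tfs$tf, cells$cell))
  for (i in seq_len(n_tf)) {
    role <- truth$tfs$role[i]
    if (role == "housekeeping") {
      a <- rep(0.5, n_cells)
    } else {
      up_branch <- if (role == "pro_PB") "PB" else "GC"
      rise <- 0.1 + 0.9 * plogis((t - x0[i]) / sl[i])
      fall <- 0.1 + 0.4 * (1 - plogis((t - x0[i]) / sl[i]))
      trunkv <- 0.1 + 0.4 * t / branch_point
      a <- ifelse(branch == up_branch, rise,
                  ifelse(branch == "trunk", trunkv, fall))
    }
    act[i, ] <- pmax(a + rnorm(n_cells, 0, nz$activity_sd), 0)
  }

  # genomic layout: regulated genes spaced far apart on one chromosome
  gene_tbl <- truth$genes
  spacing <- 2L * as.integer(truth$params$window) + 20000L
  gene_tbl$chrom <- "chrS"
  gene_tbl$tss <- 150000L + (seq_len(nrow(gene_tbl)) - 1L) * spacing
  gene_tbl$strand <- rep_len(c("+", "-"), nrow(gene_tbl))

  cres <- dplyr::left_join(truth$cres,
    gene_tbl[, c("gene", "tss", "strand")], by = "gene")
  genomic_off <- ifelse(cres$strand == "+", cres$distance, -cres$distance)
  center <- cres$tss + genomic_off
  peaks <- tibble::tibble(
    peak = cres$cre, chrom = "chrS",
    start = as.integer(pmax(center - 200L, 0L)), end = as.integer(center + 200L),
    gene = cres$gene
  )

  # peak counts: Poisson(exp(basal + sum signed strength * activity))
  edge_sign <- truth$edges
  n_peak <- nrow(peaks)
  log_rate <- matrix(log(1.5), n_peak, n_cells)
  for (j in seq_len(n_peak)) {
    bt <- cres$bound_tfs[[j]]
    if (length(bt) == 0 || cres$strength[j] == 0) next
    for (tf in bt) {
      s <- edge_sign$sign[edge_sign$tf == tf & edge_sign$gene == cres$gene[j]]
      s <- if (length(s)) s[1] else 0
      log_rate[j, ] <- log_rate[j, ] + s * cres$strength[j] * (act[tf, ] - 0.3)
    }
  }
  acc <- draw_counts(exp(log_rate), nz$nb_size)
  dimnames(acc) <- list(peaks$peak, cells$cell)

  # gene counts: Poisson(libsize * exp(alpha + beta * RP))
  w_up <- exp(-abs(cres$distance) /
    ifelse(cres$distance < 0, gene_tbl$decay_up[match(cres$gene, gene_tbl$gene)],
           gene_tbl$decay_down[match(cres$gene, gene_tbl$gene)]))
  n_gene <- nrow(gene_tbl)
  expr_rate <- matrix(0, n_gene, n_cells)
  beta_g <- numeric(n_gene)
  for (i in seq_len(n_gene)) {
    g <- gene_tbl$gene[i]
    idx <- which(cres$gene == g)
    if (length(idx) == 0) {
      expr_rate[i, ] <- 4
      next
    }
    rp <- crossprod(acc[idx, , drop = FALSE], w_up[idx])[, 1]
    s_rp <- sd(rp)
    eff <- mean(abs(truth$edges$effect[truth$edges$gene == g]))
    if (!is.finite(eff)) eff <- 0.8
    beta <- if (s_rp > 0) base_expr_effect * eff / s_rp else 0
    beta_g[i] <- beta
    expr_rate[i, ] <- exp(log(4) + beta * (rp - mean(rp)))
  }
  gene_tbl$beta <- beta_g

  # TF-coding genes: expression reads out latent activity
  tf_rate <- exp(log(3) + 1.5 * (act - 0.5))
  rate_all <- rbind(expr_rate, tf_rate) * rep(cells$libsize, each = n_gene + n_tf)
  expr <- draw_counts(rate_all, nz$nb_size)
  dimnames(expr) <- list(c(gene_tbl$gene, truth$tfs$tf), cells$cell)

  tf_genes <- tibble::tibble(
    gene = truth$tfs$tf, class = "tf", program = NA_character_,
    decay_up = NA_real_, decay_down = NA_real_,
    chrom = "chrT",
    tss = 150000L + (seq_len(n_tf) - 1L) * spacing,
    strand = "+", beta = NA_real_
  )

  structure(list(
    expr = Matrix::Matrix(expr, sparse = TRUE),
    acc = Matrix::Matrix(acc, sparse = TRUE),
    cells = cells,
    genes = dplyr::bind_rows(gene_tbl, tf_genes),
    peaks = peaks,
    tf_activity = act,
    truth = truth,
    params = list(n_cells = n_cells, branch_point = branch_point,
                  noise = nz, seed = seed)
  ), class = "multiome_dataset")
}

draw_counts <- function(rate, nb_size = NULL) {
  n <- length(rate)
  cnt <- if (is.null(nb_size)) rpois(n, rate) else
    stats::rnbinom(n, mu = rate, size = nb_size)
  matrix(cnt, nrow = nrow(rate))
}

#' @export
print.multiome_dataset <- function(x, ...) {
  cat("<multiome_dataset> ", nrow(x$expr), " genes x ", ncol(x$expr), " cells; ",
      nrow(x$acc), " peaks\n", sep = "")
  invisible(x)
}

#' TF binding interval sets from the planted truth
#'
#' Returns, for each TF, the genomic intervals of the cCREs it is bound at
#' in the truth — the synthetic analogue of a ChIP-seq binding-region set.
#'
#' @param dataset A `multiome_dataset`.
#' @return Named list (one per TF) of lists of interval tibbles
#'   (chrom, start, end), matching the shape [isd_matrix()] expects.
#' @export
tf_binding_sets <- function(dataset) {
  cres <- dataset$truth$cres
  peaks <- dataset$peaks
  sets <- lapply(dataset$truth$tfs$tf, function(tf) {
    hit <- vapply(cres$bound_tfs, function(b) tf %in% b, logical(1))
    list(peaks[match(cres$cre[hit], peaks$peak), c("chrom", "start", "end")])
  })
  names(sets) <- dataset$truth$tfs$tf
  sets
}

#' Simulate clonotypes with tunable fate concordance
#'
#' Each clone draws a fate class (PB with probability `pi_pb`), a size of
#' 1 + Poisson(rate of its fate class), and then either inherits the clone
#' fate in every cell (probability `concordance`) or assigns each cell an
#' i.i.d. Bernoulli(`pi_pb`) fate (probability 1 - `concordance`). At
#' concordance 1 no clone of size >= 2 is bifurcated; at 0 fates are fully
#' independent of clonal structure.
#'
#' @param n_clones Number of clones.
#' @param mean_size_pb,mean_size_gc Poisson rates of the size model
#'   (clone size = 1 + Poisson(rate)) for PB- and GC-class clones.
#' @param concordance Probability that a clone's cells all share its fate.
#' @param pi_pb Marginal probability of the PB fate.
#' @param seed Integer seed.
#' @return Tibble with one row per cell: `cell`, `clonotype`, `fate`.
#' @export
simulate_clonotypes <- function(n_clones, mean_size_pb = 1.5, mean_size_gc = 1.5,
                                concordance = 0, pi_pb = 0.5, seed = 1L) {
  n_clones <- assert_count(n_clones, "n_clones")
  concordance <- assert_prob(concordance, "concordance")
  pi_pb <- assert_prob(pi_pb, "pi_pb")
  if (mean_size_pb <= 0 || mean_size_gc <= 0) stop_config("clone-size rates must be > 0")
  set.seed(seed)
  if (n_clones == 0L) {
    return(tibble::tibble(cell = character(), clonotype = character(), fate = character()))
  }
  clone_fate <- ifelse(runif(n_clones) < pi_pb, "PB", "GC")
  size <- 1L + rpois(n_clones, ifelse(clone_fate == "PB", mean_size_pb, mean_size_gc))
  conc <- runif(n_clones) < concordance
  fates <- lapply(seq_len(n_clones), function(i) {
    if (conc[i]) rep(clone_fate[i], size[i])
    else ifelse(runif(size[i]) < pi_pb, "PB", "GC")
  })
  tibble::tibble(
    cell = sprintf("C%05d", seq_len(sum(size))),
    clonotype = rep(sprintf("clone%04d", seq_len(n_clones)), size),
    fate = unlist(fates)
  )
}
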