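#' Classify clonotypes by fate composition
#'
#' Clones with fewer than `min_size` cells are excluded; the rest are
#' labeled PB_only, GC_only, or bifurcated (at least one cell of each
#' fate).
#'
#' @param table Tibble with one row per cell: `cell`, `clonotype`, `fate`
#'   ("PB" or "GC").
#' @param min_size Minimum clone size counted (default 2).
#' @return A `clonotype_classes` list: `clones` (clonotype, size, n_pb,
#'   n_gc, category) and `counts` (category, n; all three categories).
#' @export
classify_clonotypes <- function(table, min_size = 2) {
  min_size <- assert_count(min_size, "min_size", min = 1L)
  bad <- setdiff(unique(table$fate), c("PB", "GC"))
  if (length(bad) > 0) {
    stop_validate(sprintf("unknown fate label(s): %s", paste(bad, collapse = ", ")))
  }
  clones <- dplyr::summarise(
    dplyr::group_by(table, .data$clonotype),
    size = dplyr::n(),
    n_pb = sum(.data$fate == "PB"),
    n_gc = sum(.data$fate == "GC"),
    .groups = "drop")
  clones <- dplyr::filter(clones, .data$size >= min_size)
  clones$category <- ifelse(clones$n_pb == clones$size, "PB_only",
                     ifelse(clones$n_gc == clones$size, "GC_only", "bifurcated"))
  cats <- c("PB_only", "GC_only", "bifurcated")
  counts <- tibble::tibble(
    category = cats,
    n = vapply(cats, function(k) sum(clones$category == k), integer(1))
  )
  structure(list(clones = clones, counts = counts, min_size = min_size),
            class = "clonotype_classes")
}

#' @export
print.clonotype_classes <- function(x, ...) {
  cat("<clonotype_classes> ", nrow(x$clones), " clones of size >= ", x$min_size,
      ": ", paste(sprintf("%s=%d", x$counts$category, x$counts$n), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo test of clonal fate concordance
#'
#' Tests whether the observed numbers of one-fate and bifurcated clonotypes
#' deviate from a fate-independence null. In `permutation` mode each
#' replicate permutes fate labels across all cells, exactly conserving the
#' clone-size multiset and the marginal fate counts. In `poisson` mode each
#' replicate redraws clone sizes as 1 + Poisson(rate) with rates fitted per
#' fate class to the observed clones, assigns fates i.i.d. at the observed
#' marginal frequency, and subsamples to the observed cell count. Category
#' z-scores compare observed to simulated counts, and
#' p = 2 * (1 - pnorm(|z|)).
#'
#' @param table Per-cell tibble: `cell`, `clonotype`, `fate`.
#' @param n_sim Number of Monte-Carlo replicates (default 1000).
#' @param mode "permutation" (default) or "poisson".
#' @param seed Integer seed; replicate streams are derived from it.
#' @param min_size Minimum clone size counted.
#' @return A `clonal_test` tibble: category, observed, sim_mean, sim_sd, z,
#'   p, degenerate; attributes n_sim, mode, seed, min_size.
#' @export
clonal_null_test <- function(table, n_sim = 1000,
                             mode = c("permutation", "poisson"), seed = 1L,
                             min_size = 2) {
  mode <- match.arg(mode)
  n_sim <- assert_count(n_sim, "n_sim", min = 1L)
  obs <- classify_clonotypes(table, min_size = min_size)
  if (nrow(obs$clones) < 2) {
    stop_validate("need at least 2 clones of qualifying size")
  }
  if (length(unique(table$fate)) < 2) {
    stop_validate("both PB and GC fates must be present")
  }

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_sim)
  sim <- matrix(0L, n_sim, 3L,
                dimnames = list(NULL, c("PB_only", "GC_only", "bifurcated")))

  if (mode == "permutation") {
    clone_of <- match(table$clonotype, unique(table$clonotype))
    is_pb <- as.integer(table$fate == "PB")
    size <- tabulate(clone_of)
    qualif <- size >= min_size
    for (r in seq_len(n_sim)) {
      set.seed(rep_seeds[r])
      perm <- is_pb[sample.int(length(is_pb))]
      pb_per_clone <- rowsum_int(perm, clone_of, length(size))
      s <- pb_per_clone[qualif]
      sz <- size[qualif]
      sim[r, ] <- c(sum(s == sz), sum(s == 0L), sum(s > 0L & s < sz))
    }
  } else {
    all_clones <- dplyr::summarise(
      dplyr::group_by(table, .data$clonotype),
      size = dplyr::n(), n_pb = sum(.data$fate == "PB"), .groups = "drop")
    cls_pb <- all_clones$n_pb * 2L >= all_clones$size # majority fate, ties to PB
    lam_pb <- max(mean(all_clones$size[cls_pb] - 1L), 1e-6)
    lam_gc <- max(mean(all_clones$size[!cls_pb] - 1L), 1e-6)
    n_pb_clones <- sum(cls_pb); n_gc_clones <- sum(!cls_pb)
    p_pb <- mean(table$fate == "PB")
    n_cells <- nrow(table)
    for (r in seq_len(n_sim)) {
      set.seed(rep_seeds[r])
      sizes <- c(1L + rpois(n_pb_clones, lam_pb), 1L + rpois(n_gc_clones, lam_gc))
      clone_id <- rep.int(seq_along(sizes), sizes)
      if (length(clone_id) > n_cells) {
        clone_id <- clone_id[sort(sample.int(length(clone_id), n_cells))]
      }
      fate_pb <- as.integer(runif(length(clone_id)) < p_pb)
      sz <- tabulate(clone_id, nbins = length(sizes))
      s <- rowsum_int(fate_pb, clone_id, length(sizes))
      qual <- sz >= min_size
      sim[r, ] <- c(sum(s[qual] == sz[qual]), sum(s[qual] == 0L),
                    sum(s[qual] > 0L & s[qual] < sz[qual]))
    }
  }

  observed <- setNames(obs$counts$n, obs$counts$category)
  out <- purrr::map_dfr(colnames(sim), function(cat) {
    m <- mean(sim[, cat]); s <- sd(sim[, cat]); o <- observed[[cat]]
    if (s == 0) {
      tibble::tibble(category = cat, observed = o, sim_mean = m, sim_sd = s,
                     z = if (o == m) 0 else sign(o - m) * Inf,
                     p = if (o == m) 1 else 0, degenerate = TRUE)
    } else {
      z <- (o - m) / s
      tibble::tibble(category = cat, observed = o, sim_mean = m, sim_sd = s,
                     z = z, p = 2 * (1 - pnorm(abs(z))), degenerate = FALSE)
    }
  })
  attr(out, "n_sim") <- n_sim
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "min_size") <- min_size
  attr(out, "sim_counts") <- sim
  class(out) <- c("clonal_test", class(out))
  out
}

rowsum_int <- function(x, group, n_groups) {
  out <- rep(0L, n_groups)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  out
}
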