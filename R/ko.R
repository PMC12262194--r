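#' Simulate a transcription-factor knockout by network propagation
#'
#' Sets the TF's (normalized) expression to zero in every cell and
#' propagates the shift through the state-specific weight matrix for
#' `n_steps` rounds (primary, secondary, tertiary targets at the default 3).
#' After each step the simulated expression is clamped at zero and the
#' knocked-out TF re-clamped to zero. Cells in states without a fitted
#' network get a zero shift.
#'
#' @param edges An `edge_tbl` or list of them (round-2 rows are used).
#' @param expr Normalized gene x cell expression.
#' @param states Per-cell state labels aligned with `colnames(expr)`.
#' @param tf TF to knock out (must appear in the networks and in `expr`).
#' @param n_steps Propagation depth (>= 1).
#' @return Gene x cell matrix of expression shifts (the knockout minus the
#'   observed state).
#' @export
simulate_ko <- function(edges, expr, states, tf, n_steps = 3) {
  fin <- final_edges(edges)
  n_steps <- assert_count(n_steps, "n_steps", min = 1L)
  E <- as.matrix(expr)
  if (!tf %in% rownames(E)) stop_validate(sprintf("TF '%s' absent from expression", tf))
  if (!tf %in% fin$tf) stop_validate(sprintf("TF '%s' absent from the fitted networks", tf))
  stopifnot(length(states) == ncol(E))

  genes <- rownames(E)
  total <- matrix(0, nrow(E), ncol(E), dimnames = dimnames(E))
  for (s in unique(states)) {
    cells <- which(states == s)
    e <- fin[fin$state == s & fin$tf %in% genes & fin$gene %in% genes, ]
    if (nrow(e) == 0) next # no fitted network for this state: zero shift
    X <- E[, cells, drop = FALSE]
    accum <- matrix(0, nrow(E), length(cells))
    accum[match(tf, genes), ] <- -X[tf, ]
    if (nrow(e) > 0) {
      W <- Matrix::sparseMatrix(
        i = match(e$gene, genes), j = match(e$tf, genes), x = e$weight,
        dims = c(length(genes), length(genes)))
      d_prev <- accum
      for (k in seq_len(n_steps)) {
        d_k <- as.matrix(W %*% d_prev)
        sim <- X + accum + d_k
        sim <- pmax(sim, 0)
        sim[match(tf, genes), ] <- 0
        d_k <- sim - X - accum
        accum <- accum + d_k
        d_prev <- d_k
        if (all(d_k == 0)) break
      }
    }
    total[, cells] <- accum
  }
  total
}

#' Perturbation scores against the differentiation flow
#'
#' The per-cell perturbation score is the dot product of the perturbation
#' flow vector and the differentiation flow vector. Net scores sum the
#' per-cell scores over the GC and PB cell sets, and
#' delta_ps = net_gc - net_pb: positive when the knockout pushes cells
#' toward the GC fate relative to PB (the signature of knocking out a
#' PB-promoting TF).
#'
#' @param pfield Perturbation `vector_field`.
#' @param dfield Differentiation `vector_field` over the same cells.
#' @param gc_cells,pb_cells Disjoint cell-ID sets of the two fate clusters.
#' @return A `perturbation_result`: `cells` tibble (cell, ps), `net_gc`,
#'   `net_pb`, `delta_ps`.
#' @export
perturbation_scores <- function(pfield, dfield, gc_cells, pb_cells) {
  stopifnot(inherits(pfield, "vector_field"), inherits(dfield, "vector_field"))
  if (!identical(pfield$cells$cell, dfield$cells$cell)) {
    stop_validate("perturbation and differentiation fields must share the cell index")
  }
  both <- intersect(gc_cells, pb_cells)
  if (length(both) > 0) {
    stop_validate(sprintf("cell(s) in both fate sets: %s",
                          paste(utils::head(both, 3), collapse = ", ")))
  }
  ps <- pfield$cells$vx * dfield$cells$vx + pfield$cells$vy * dfield$cells$vy
  cells <- tibble::tibble(cell = pfield$cells$cell, ps = ps)
  net_gc <- sum(ps[cells$cell %in% gc_cells])
  net_pb <- sum(ps[cells$cell %in% pb_cells])
  structure(list(cells = cells, net_gc = net_gc, net_pb = net_pb,
                 delta_ps = net_gc - net_pb),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result> net GC = ", signif(x$net_gc, 4),
      ", net PB = ", signif(x$net_pb, 4),
      ", delta = ", signif(x$delta_ps, 4), "\n", sep = "")
  invisible(x)
}

#' Run the knockout -> flow -> score pipeline for one TF
#'
#' Convenience wrapper chaining [simulate_ko()], [perturbation_flow()] and
#' [perturbation_scores()] against a precomputed differentiation field.
#'
#' @param edges Fitted `edge_tbl`(s).
#' @param expr Normalized gene x cell expression.
#' @param cells Cell metadata tibble with `cell`, `state`, `x`, `y`.
#' @param tf TF to knock out.
#' @param dfield Differentiation `vector_field` (from
#'   [differentiation_flow()]).
#' @param gc_states,pb_states State labels forming the GC and PB clusters.
#' @param k_neighbors,temperature,n_steps Passed through.
#' @return A `perturbation_result` with the TF recorded as attribute.
#' @export
score_tf_ko <- function(edges, expr, cells, tf, dfield,
                        gc_states = "GC", pb_states = "PB",
                        k_neighbors = 200, temperature = 0.05, n_steps = 3) {
  delta <- simulate_ko(edges, expr, cells$state, tf, n_steps = n_steps)
  pf <- perturbation_flow(delta, expr, cells[, c("cell", "x", "y")],
                          k_neighbors = k_neighbors, temperature = temperature)
  res <- perturbation_scores(pf, dfield,
                             gc_cells = cells$cell[cells$state %in% gc_states],
                             pb_cells = cells$cell[cells$state %in% pb_states])
  attr(res, "tf") <- tf
  res
}
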