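#' TF eigenvector centralities across cell states
#'
#' Builds, for each state, an undirected graph over TFs and genes with edge
#' magnitude |weight| from the final (round-2) edges, computes the principal
#' eigenvector by power iteration (tolerance 1e-10), and reports the TF
#' rows. Each per-state centrality vector is nonnegative with unit Euclidean
#' norm over all nodes. The scaled form standardizes each TF across states.
#'
#' @param edges An `edge_tbl` or a list of them (one per state).
#' @return A `centrality_matrix`: list with `centrality` (TF x state),
#'   `scaled` (per-TF z-scores across states), `node_vectors` (full
#'   unit-norm per-state vectors over TF and gene nodes), `zero_states`
#'   (states whose graph was empty/all-zero).
#' @export
tf_centrality <- function(edges) {
  fin <- final_edges(edges)
  if (nrow(fin) == 0) stop_validate("no final (round-2) edges to analyze")
  states <- unique(fin$state)
  tfs <- sort(unique(fin$tf))
  cent <- matrix(0, length(tfs), length(states), dimnames = list(tfs, states))
  zero_states <- character(0)
  node_vectors <- list()
  for (s in states) {
    e <- fin[fin$state == s, ]
    nodes <- sort(unique(c(e$tf, e$gene)))
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    A[cbind(e$tf, e$gene)] <- abs(e$weight)
    A <- A + t(A)
    v <- power_iteration(A)
    if (is.null(v)) {
      zero_states <- c(zero_states, s)
      next
    }
    node_vectors[[s]] <- v
    common <- intersect(tfs, nodes)
    cent[common, s] <- v[common]
  }
  scaled <- cent * 0
  for (i in seq_len(nrow(cent))) {
    x <- cent[i, ]
    s <- sd(x)
    if (length(x) >= 2 && s > 0) scaled[i, ] <- (x - mean(x)) / s
  }
  structure(list(centrality = cent, scaled = scaled,
                 node_vectors = node_vectors, zero_states = zero_states),
            class = "centrality_matrix")
}

power_iteration <- function(A, tol = 1e-10, max_iter = 10000) {
  n <- nrow(A)
  if (n == 0 || all(A == 0)) return(NULL)
  # diagonal shift keeps the principal eigenvector but guarantees convergence
  # on bipartite graphs (whose spectrum is symmetric about zero)
  shift <- max(rowSums(abs(A)))
  As <- A + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- As %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(NULL)
    w <- as.numeric(w) / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  setNames(pmax(v, 0) / sqrt(sum(pmax(v, 0)^2)), rownames(A))
}

#' @export
print.centrality_matrix <- function(x, ...) {
  cat("<centrality_matrix> ", nrow(x$centrality), " TFs x ",
      ncol(x$centrality), " states\n", sep = "")
  invisible(x)
}

#' Cluster TFs by their scaled centrality profiles
#'
#' k-means (50 restarts, seeded) on the per-TF standardized centrality
#' profiles across states.
#'
#' @param cm A `centrality_matrix`.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed; labels are deterministic given the seed.
#' @return Tibble: `tf`, `cluster` (1..k), with the kmeans fit as attribute
#'   `fit`.
#' @export
centrality_clusters <- function(cm, k = 6, seed = 1L) {
  stopifnot(inherits(cm, "centrality_matrix"))
  k <- assert_count(k, "k", min = 1L)
  if (k > nrow(cm$scaled)) {
    stop_validate(sprintf("k = %d exceeds the number of TFs (%d)", k, nrow(cm$scaled)))
  }
  set.seed(seed)
  fit <- kmeans(cm$scaled, centers = k, nstart = 50)
  out <- tibble::tibble(tf = rownames(cm$scaled),
                        cluster = as.integer(fit$cluster))
  attr(out, "fit") <- fit
  out
}
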