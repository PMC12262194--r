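#' Differentiation flow field from pseudotime
#'
#' Bins cells on a grid over the embedding bounding box, averages pseudotime
#' per occupied bin, takes the 2-D central-difference gradient over occupied
#' bins (one-sided at occupancy borders), smooths it with a Gaussian kernel,
#' and assigns each cell its bin's vector. Cells in bins with no occupied
#' neighborhood get a zero vector.
#'
#' @param embedding Per-cell coordinates: data frame with `x`, `y` (and
#'   optionally `cell`), or a 2-column matrix.
#' @param pseudotime Per-cell pseudotime, finite.
#' @param grid_n Bins per axis (default 40).
#' @param smooth Gaussian kernel width in bins (default 1).
#' @return A `vector_field`: `cells` tibble (cell, x, y, vx, vy), `grid`
#'   list (vx, vy, mask, mean_pt matrices and axis breaks), `kind`.
#' @export
differentiation_flow <- function(embedding, pseudotime, grid_n = 40, smooth = 1) {
  emb <- as_embedding(embedding)
  n <- nrow(emb)
  stopifnot(length(pseudotime) == n)
  if (any(!is.finite(pseudotime))) stop_validate("pseudotime must be finite")
  grid_n <- assert_count(grid_n, "grid_n", min = 2L)

  xb <- seq(min(emb$x), max(emb$x), length.out = grid_n + 1L)
  yb <- seq(min(emb$y), max(emb$y), length.out = grid_n + 1L)
  bx <- pmin(pmax(findInterval(emb$x, xb, all.inside = TRUE), 1L), grid_n)
  by <- pmin(pmax(findInterval(emb$y, yb, all.inside = TRUE), 1L), grid_n)

  M <- matrix(NA_real_, grid_n, grid_n)
  cnt <- matrix(0L, grid_n, grid_n)
  for (i in seq_len(n)) {
    cnt[bx[i], by[i]] <- cnt[bx[i], by[i]] + 1L
    M[bx[i], by[i]] <- if (is.na(M[bx[i], by[i]])) pseudotime[i] else
      M[bx[i], by[i]] + pseudotime[i]
  }
  occ <- cnt > 0L
  M[occ] <- M[occ] / cnt[occ]
  if (sum(occ) <= 1L) {
    rlang::warn("all cells fall in a single occupied bin; returning a zero field")
    zero <- matrix(0, grid_n, grid_n)
    return(new_vector_field(emb, rep(0, n), rep(0, n),
                            list(vx = zero, vy = zero, mask = occ, mean_pt = M,
                                 xb = xb, yb = yb), "differentiation"))
  }

  dx <- (xb[grid_n + 1L] - xb[1L]) / grid_n
  dy <- (yb[grid_n + 1L] - yb[1L]) / grid_n
  gx <- grad_axis(M, occ, dx, along_rows = TRUE)
  gy <- grad_axis(M, occ, dy, along_rows = FALSE)
  gx <- smooth_masked(gx, occ, smooth)
  gy <- smooth_masked(gy, occ, smooth)

  vx <- gx[cbind(bx, by)]
  vy <- gy[cbind(bx, by)]
  vx[is.na(vx)] <- 0; vy[is.na(vy)] <- 0
  new_vector_field(emb, vx, vy,
                   list(vx = gx, vy = gy, mask = occ, mean_pt = M, xb = xb, yb = yb),
                   "differentiation")
}

as_embedding <- function(embedding) {
  if (is.matrix(embedding)) {
    emb <- tibble::tibble(x = embedding[, 1], y = embedding[, 2])
    emb$cell <- rownames(embedding) %||% sprintf("cell%d", seq_len(nrow(emb)))
  } else {
    emb <- tibble::as_tibble(embedding)
    stopifnot(all(c("x", "y") %in% names(emb)))
    if (!"cell" %in% names(emb)) emb$cell <- sprintf("cell%d", nrow(emb) |> seq_len())
  }
  emb[, c("cell", "x", "y")]
}

# central differences along one axis over occupied bins, one-sided at borders
grad_axis <- function(M, occ, step, along_rows) {
  n <- nrow(M)
  G <- matrix(0, n, n)
  get <- function(i, j) if (i >= 1 && i <= n && j >= 1 && j <= n && occ[i, j]) M[i, j] else NA_real_
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!occ[i, j]) next
    if (along_rows) { lo <- get(i - 1L, j); hi <- get(i + 1L, j) }
    else            { lo <- get(i, j - 1L); hi <- get(i, j + 1L) }
    G[i, j] <- if (!is.na(lo) && !is.na(hi)) (hi - lo) / (2 * step)
      else if (!is.na(hi)) (hi - M[i, j]) / step
      else if (!is.na(lo)) (M[i, j] - lo) / step
      else 0
  }
  G
}

# Gaussian smoothing restricted to occupied bins (mask-normalized)
smooth_masked <- function(G, occ, sigma) {
  if (sigma <= 0) return(G)
  n <- nrow(G)
  r <- max(1L, ceiling(3 * sigma))
  ker <- outer(-r:r, -r:r, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!occ[i, j]) next
    ii <- max(1L, i - r):min(n, i + r)
    jj <- max(1L, j - r):min(n, j + r)
    kw <- ker[ii - i + r + 1L, jj - j + r + 1L, drop = FALSE]
    m <- occ[ii, jj, drop = FALSE]
    w <- kw * m
    out[i, j] <- sum(w * G[ii, jj]) / sum(w)
  }
  out
}

new_vector_field <- function(emb, vx, vy, grid, kind) {
  structure(list(
    cells = tibble::tibble(cell = emb$cell, x = emb$x, y = emb$y, vx = vx, vy = vy),
    grid = grid, kind = kind
  ), class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat("<vector_field> kind=", x$kind, ", ", nrow(x$cells), " cells, mean |v| = ",
      signif(mean(sqrt(x$cells$vx^2 + x$cells$vy^2)), 3), "\n", sep = "")
  invisible(x)
}

#' Embed gene-space knockout shifts as a flow over the embedding
#'
#' For each cell, transition probabilities over its k nearest embedding
#' neighbors are a softmax (temperature `temperature`) of the Pearson
#' correlation between the cell's knockout shift and each neighbor's
#' expression difference; the cell's vector is the probability-weighted mean
#' displacement minus the uniform-neighbor baseline. Cells with an all-zero
#' shift get a zero vector.
#'
#' @param delta Gene x cell knockout shift (from [simulate_ko()]).
#' @param expr Normalized gene x cell expression used for the fit.
#' @param embedding Per-cell coordinates (see [differentiation_flow()]).
#' @param k_neighbors Neighborhood size (< number of cells).
#' @param temperature Softmax temperature on the correlations.
#' @return A `vector_field` of kind "perturbation".
#' @export
perturbation_flow <- function(delta, expr, embedding, k_neighbors = 200,
                              temperature = 0.05) {
  emb <- as_embedding(embedding)
  n <- nrow(emb)
  k_neighbors <- assert_count(k_neighbors, "k_neighbors", min = 1L)
  if (k_neighbors >= n) stop_config("`k_neighbors` must be < the number of cells")
  delta <- as.matrix(delta); E <- as.matrix(expr)
  stopifnot(ncol(delta) == n, ncol(E) == n, nrow(delta) == nrow(E))

  P <- cbind(emb$x, emb$y)
  D2 <- as.matrix(stats::dist(P))^2
  vx <- numeric(n); vy <- numeric(n)
  for (c in seq_len(n)) {
    dc <- delta[, c]
    if (all(dc == 0)) next
    nb <- order(D2[c, ])[2:(k_neighbors + 1L)]
    X <- E[, nb, drop = FALSE] - E[, c]
    r <- suppressWarnings(as.numeric(stats::cor(dc, X)))
    r[is.na(r)] <- 0
    w <- exp((r - max(r)) / temperature)
    w <- w / sum(w)
    dxs <- P[nb, 1] - P[c, 1]
    dys <- P[nb, 2] - P[c, 2]
    vx[c] <- sum(w * dxs) - mean(dxs)
    vy[c] <- sum(w * dys) - mean(dys)
  }
  new_vector_field(emb, vx, vy, grid = NULL, kind = "perturbation")
}
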